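# Full simulated-study driver: N participants x 3 models x 3 experiments
# (motion-restricted CV, motion-unrestricted CV, restricted-trained models on
# a continuous realistic block).

#' Configuration of a simulated workload study
#'
#' Bundles every tunable of the simulation and evaluation protocol. Defaults
#' reproduce the reference paradigm: two training blocks of nine 30 s task and
#' nine 30 s rest trials separated by 30 s fixation crosses (one block
#' motion-restricted, one motion-unrestricted), a continuous realistic block
#' (3.5 min rest / 3.5 min task / 3.5 min rest), 6.25 Hz sampling, nine-fold
#' cross-validation, and inter-participant variability as a lognormal
#' amplitude gain (sdlog 0.25) plus uniform onset-lag jitter on 1--2 s.
#'
#' @param n_participants Number of simulated participants.
#' @param seed Master seed; all per-participant seeds derive from it.
#' @param rate Sampling rate (Hz).
#' @param n_task,n_rest,trial_dur,fixation_dur Training-block paradigm, see
#'   [generate_paradigm()].
#' @param k Cross-validation folds.
#' @param alpha Significance level.
#' @param chance Chance accuracy level.
#' @param hdr,noise [hdr_params()] / [noise_params()] population defaults.
#' @param motion_restricted,motion_unrestricted,motion_realistic Per-block
#'   [motion_params()].
#' @param filter [filter_settings()] for preprocessing.
#' @param window_duration Window-SVM window (seconds); defaults to
#'   `trial_dur`.
#' @param stride Sliding-window stride (seconds) on continuous data.
#' @param cost SVM cost.
#' @param gain_sdlog sdlog of the lognormal per-participant amplitude gain.
#' @param lag_jitter Range (seconds) of the uniform per-participant onset lag.
#' @param permute_labels Permute trial labels before cross-validation
#'   (permutation-null studies)?
#' @param persistence Consecutive-sample requirement for onset detection.
#' @param experiments Subset of
#'   `c("restricted_cv", "unrestricted_cv", "realistic")` to run.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_participants = 20, seed = 1L, rate = 6.25,
                         n_task = 9, n_rest = 9, trial_dur = 30,
                         fixation_dur = 30, k = 9, alpha = 0.05,
                         chance = 0.5, hdr = hdr_params(),
                         noise = noise_params(),
                         motion_restricted = motion_none(),
                         motion_unrestricted = motion_params(),
                         motion_realistic = motion_params(),
                         filter = filter_settings(),
                         window_duration = trial_dur, stride = 1, cost = 1,
                         gain_sdlog = 0.25, lag_jitter = c(1, 2),
                         permute_labels = FALSE, persistence = 1L,
                         experiments = c("restricted_cv", "unrestricted_cv",
                                         "realistic")) {
  if (!is_scalar_count(n_participants) || n_participants < 1) {
    stop("`n_participants` must be a positive integer", call. = FALSE)
  }
  if (!is_scalar_count(seed)) stop("`seed` must be an integer", call. = FALSE)
  stopifnot(inherits(hdr, "hdr_params"), inherits(noise, "noise_params"),
            inherits(motion_restricted, "motion_params"),
            inherits(motion_unrestricted, "motion_params"),
            inherits(motion_realistic, "motion_params"),
            inherits(filter, "filter_settings"))
  if (!is.numeric(lag_jitter) || length(lag_jitter) != 2L ||
      lag_jitter[1] > lag_jitter[2]) {
    stop("`lag_jitter` must be an increasing numeric pair (seconds)",
         call. = FALSE)
  }
  experiments <- match.arg(experiments,
                           c("restricted_cv", "unrestricted_cv", "realistic"),
                           several.ok = TRUE)
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed), rate = rate, n_task = n_task,
                 n_rest = n_rest, trial_dur = trial_dur,
                 fixation_dur = fixation_dur, k = k, alpha = alpha,
                 chance = chance, hdr = hdr, noise = noise,
                 motion_restricted = motion_restricted,
                 motion_unrestricted = motion_unrestricted,
                 motion_realistic = motion_realistic, filter = filter,
                 window_duration = window_duration, stride = stride,
                 cost = cost, gain_sdlog = gain_sdlog,
                 lag_jitter = lag_jitter,
                 permute_labels = isTRUE(permute_labels),
                 persistence = persistence, experiments = experiments),
            class = "study_config")
}

simulate_study_participant <- function(config, seed_p) {
  with_seed(seed_p, {
    # the participant gain models optode-scalp coupling and cortical
    # responsiveness, which scale all hemodynamic components alike (the
    # instrument's white noise is unaffected)
    gain <- stats::rlnorm(1, 0, config$gain_sdlog)
    lag <- stats::runif(1, config$lag_jitter[1], config$lag_jitter[2])
    hdr_p <- config$hdr
    hdr_p$hbo_amplitude <- hdr_p$hbo_amplitude * gain
    hdr_p$onset_lag <- lag
    noise_p <- config$noise
    for (comp in c("cardiac", "respiration", "mayer", "drift",
                   "spontaneous")) {
      noise_p[[comp]][2] <- noise_p[[comp]][2] * gain
    }
    par_seeds <- sample.int(.Machine$integer.max, 4L)
    list(hdr = hdr_p, noise = noise_p, seeds = par_seeds)
  })
}

run_participant <- function(config, seed_p, participant_id) {
  pp <- simulate_study_participant(config, seed_p)
  ex <- config$experiments
  # the restricted block also trains the models evaluated on the realistic one
  need <- c("restricted"[any(c("restricted_cv", "realistic") %in% ex)],
            "unrestricted"["unrestricted_cv" %in% ex],
            "realistic"["realistic" %in% ex])
  paradigms <- list(
    restricted = generate_paradigm("training_block", config$n_task,
                                   config$n_rest, config$trial_dur,
                                   config$fixation_dur, seed = pp$seeds[1],
                                   block = "restricted"),
    unrestricted = generate_paradigm("training_block", config$n_task,
                                     config$n_rest, config$trial_dur,
                                     config$fixation_dur, seed = pp$seeds[2],
                                     block = "unrestricted"),
    realistic = generate_paradigm("realistic", block = "realistic"))[need]
  ds <- generate_participant(
    paradigms, hdr = pp$hdr, noise = pp$noise,
    motion_by_block = list(restricted = config$motion_restricted,
                           unrestricted = config$motion_unrestricted,
                           realistic = config$motion_realistic)[need],
    rate = config$rate, seed = pp$seeds[3])
  prep <- lapply(ds$recordings, preprocess_pipeline, settings = config$filter)

  models <- c("threshold", "pointwise", "window")
  rows <- list()
  acc <- list()
  perm_seed <- if (config$permute_labels) pp$seeds[4] else NULL
  for (block in intersect(c("restricted", "unrestricted"),
                          sub("_cv$", "", ex))) {
    for (mdl in models) {
      cv <- crossvalidate(prep[[block]], ds$trials[[block]], model = mdl,
                          k = config$k,
                          window_duration = config$window_duration,
                          cost = config$cost, permute_seed = perm_seed,
                          persistence = config$persistence)
      sig <- per_participant_significance(cv$n_correct, cv$n_trials,
                                          config$chance, config$alpha)
      lat <- cv$latencies[!is.na(cv$latencies)]
      rows[[length(rows) + 1L]] <- data.frame(
        participant = participant_id, model = mdl,
        experiment = paste0(block, "_cv"), accuracy = cv$accuracy,
        n_correct_trials = cv$n_correct, n_trials = cv$n_trials,
        significant = sig$significant,
        mean_latency_s = if (length(lat)) mean(lat) else NA_real_,
        stringsAsFactors = FALSE)
      acc[[paste(mdl, block, sep = ".")]] <- cv$accuracy
    }
  }
  if (!"realistic" %in% ex) {
    return(do.call(rbind, rows))
  }
  # realistic evaluation: models trained on the full motion-restricted block
  fitted <- list(
    threshold = fit_threshold(prep$restricted, ds$trials$restricted),
    pointwise = fit_svm(featurize_pointwise(prep$restricted,
                                            ds$trials$restricted),
                        "pointwise", cost = config$cost),
    window = fit_svm(featurize_window(prep$restricted, ds$trials$restricted,
                                      config$window_duration),
                     "window", cost = config$cost))
  realistic <- evaluate_realistic(prep$realistic, ds$trials$realistic, fitted,
                                  stride = config$stride,
                                  persistence = config$persistence)
  for (i in seq_len(nrow(realistic))) {
    rows[[length(rows) + 1L]] <- data.frame(
      participant = participant_id, model = realistic$model[i],
      experiment = "realistic", accuracy = realistic$accuracy[i],
      n_correct_trials = NA_integer_, n_trials = NA_integer_,
      significant = NA, mean_latency_s = realistic$latency_s[i],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run a full simulated workload study
#'
#' Simulates `config$n_participants` participants and executes the three
#' experiments for each of the three models: cross-validation on the
#' motion-restricted training block, cross-validation on the
#' motion-unrestricted block, and evaluation of restricted-trained models on
#' the continuous realistic block. Fully seeded: identical configurations
#' yield identical reports.
#'
#' @param config A [study_config()].
#' @param progress Print one line per participant?
#' @return An object of class `study_report`: `per_participant` (data frame),
#'   `summary` (group statistics per model and experiment), `comparisons`
#'   (paired pointwise-vs-window tests per experiment), `latency` (summary of
#'   the thresholding model's onset latencies), and the `config`.
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max, config$n_participants))
  per <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    per[[p]] <- run_participant(config, seeds[p], p)
    if (progress) {
      message(sprintf("participant %d/%d done", p, config$n_participants))
    }
  }
  per_participant <- do.call(rbind, per)

  experiments <- unique(per_participant$experiment)
  models <- unique(per_participant$model)
  summ <- list()
  for (ex in experiments) {
    for (mdl in models) {
      sel <- per_participant$experiment == ex & per_participant$model == mdl
      gs <- group_stats(per_participant$accuracy[sel], config$chance,
                        config$alpha)
      summ[[length(summ) + 1L]] <- data.frame(
        model = mdl, experiment = ex, n = gs$n, mean_acc = gs$mean,
        sd_acc = gs$sd, t = gs$t, df = gs$df, p = gs$p,
        n_significant = sum(per_participant$significant[sel], na.rm = TRUE),
        mean_latency_s = mean(per_participant$mean_latency_s[sel],
                              na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  summary_df <- do.call(rbind, summ)

  comparisons <- lapply(stats::setNames(experiments, experiments),
                        function(ex) {
    a <- per_participant[per_participant$experiment == ex &
                           per_participant$model == "pointwise", ]
    b <- per_participant[per_participant$experiment == ex &
                           per_participant$model == "window", ]
    compare_models(a$accuracy[order(a$participant)],
                   b$accuracy[order(b$participant)])
  })

  thr <- per_participant[per_participant$model == "threshold" &
                           per_participant$experiment == "restricted_cv", ]
  latency <- if (any(!is.na(thr$mean_latency_s))) {
    latency_stats(thr$mean_latency_s)
  } else NULL

  structure(list(per_participant = per_participant, summary = summary_df,
                 comparisons = comparisons, latency = latency,
                 config = config, participant_seeds = seeds),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> N = %d participants, seed %d%s\n",
              x$config$n_participants, x$config$seed,
              if (x$config$permute_labels) " (label-permuted null)" else ""))
  df <- x$summary
  df$mean_acc <- sprintf("%.1f%%", 100 * df$mean_acc)
  df$sd_acc <- sprintf("%.1f%%", 100 * df$sd_acc)
  df$t <- sprintf("%.2f", df$t)
  df$p <- format.pval(df$p, digits = 3)
  df$mean_latency_s <- ifelse(is.na(df$mean_latency_s), "",
                              sprintf("%.1f", df$mean_latency_s))
  print(df, row.names = FALSE)
  if (!is.null(x$latency)) {
    cat(sprintf(
      "thresholding onset latency (restricted CV): %.1f (+/- %.1f) s, range %.1f-%.1f s, %d/%d with detections\n",
      x$latency$mean, x$latency$sd, x$latency$min, x$latency$max,
      x$latency$n, x$latency$n + x$latency$n_none))
  }
  cat("note: no multiple-testing correction across models\n")
  invisible(x)
}
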