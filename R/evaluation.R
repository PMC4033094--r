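# Evaluation protocol: per-participant cross-validation, group statistics
# against chance, paired model comparisons, continuous-monitoring evaluation,
# and onset-latency summaries.

#' Score a prediction series against trial labels
#'
#' Each predicted timepoint falling inside a task or rest trial is scored
#' against that trial's condition; predictions outside any task/rest trial are
#' ignored.
#'
#' @param pred A `prediction_series`.
#' @param trials A [trial_table()].
#' @return List with `accuracy`, `n_correct`, `n_total`, and a per-trial data
#'   frame `by_trial` (columns `condition`, `n`, `n_correct`,
#'   `majority_correct`; ties in the majority vote count as incorrect).
#' @export
score_predictions <- function(pred, trials) {
  validate_trial_table(trials)
  tt <- nonfixation_trials(trials)
  per_trial <- lapply(seq_len(nrow(tt)), function(i) {
    sel <- pred$time >= tt$onset_s[i] - 1e-9 &
      pred$time < tt$onset_s[i] + tt$duration_s[i] - 1e-9
    labs <- pred$label[sel]
    n <- length(labs)
    n_corr <- sum(labs == tt$condition[i])
    data.frame(condition = tt$condition[i], n = n, n_correct = n_corr,
               majority_correct = n > 0 && n_corr > n / 2)
  })
  by_trial <- do.call(rbind, per_trial)
  scored <- by_trial[by_trial$n > 0, , drop = FALSE]
  n_total <- sum(scored$n)
  n_correct <- sum(scored$n_correct)
  list(accuracy = if (n_total > 0) n_correct / n_total else NA_real_,
       n_correct = n_correct, n_total = n_total, by_trial = by_trial)
}

fit_model_on_trials <- function(rec, trials, model, window_duration, cost) {
  switch(model,
         threshold = fit_threshold(rec, trials),
         pointwise = fit_svm(featurize_pointwise(rec, trials), "pointwise",
                             cost = cost),
         window = fit_svm(featurize_window(rec, trials, window_duration),
                          "window", cost = cost))
}

#' Per-participant k-fold cross-validation of one workload model
#'
#' Task and rest trials are each split (in onset order) into `k` folds, so the
#' default `k = 9` on a nine-task/nine-rest block holds out exactly one task
#' and one rest trial per fold. For each fold the model is refitted on the
#' remaining trials only and evaluated on the held-out trials; no samples from
#' held-out trials influence fitting. Accuracy pools correct timepoint labels
#' (threshold and pointwise models) or trial labels (window model) over all
#' folds. Trial-level outcomes (majority vote over a trial's timepoints) and
#' onset latencies of held-out task trials are also returned.
#'
#' @param rec A preprocessed [hemo_recording()].
#' @param trials A [trial_table()] with equal numbers of task and rest trials
#'   divisible by `k`.
#' @param model `"threshold"`, `"pointwise"` or `"window"`.
#' @param k Number of folds (default 9).
#' @param window_duration Window length (seconds) for the window model;
#'   defaults to the shortest task/rest trial.
#' @param cost SVM cost parameter.
#' @param permute_seed When non-`NULL`, trial condition labels are permuted
#'   under this seed before cross-validation (a permutation-null run).
#' @param persistence Consecutive-sample requirement for [detect_onset()].
#' @return An object of class `cv_result`: `accuracy`, trial-level
#'   `n_correct` / `n_trials`, per-task-trial `latencies` (seconds, `NA` when
#'   no detection), and the fold assignment.
#' @export
crossvalidate <- function(rec, trials,
                          model = c("threshold", "pointwise", "window"),
                          k = 9, window_duration = NULL, cost = 1,
                          permute_seed = NULL, persistence = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(rec, "hemo_recording"))
  validate_trial_table(trials)
  tt <- nonfixation_trials(trials)
  if (!is.null(permute_seed)) {
    tt$condition <- with_seed(permute_seed, sample(tt$condition))
  }
  n_task <- sum(tt$condition == "task")
  n_rest <- sum(tt$condition == "rest")
  if (!is_scalar_count(k) || k < 2) {
    stop("`k` must be an integer >= 2", call. = FALSE)
  }
  if (n_task == 0 || n_rest == 0) {
    stop("cross-validation needs both task and rest trials", call. = FALSE)
  }
  if (n_task %% k != 0 || n_rest %% k != 0) {
    divs <- Filter(function(d) n_task %% d == 0 && n_rest %% d == 0,
                   2:max(2, min(n_task, n_rest)))
    stop(sprintf(
      "k = %d does not divide the trial counts (%d task, %d rest); valid k: %s",
      k, n_task, n_rest,
      if (length(divs)) paste(divs, collapse = ", ") else "none"),
      call. = FALSE)
  }
  wd <- window_duration %||% min(tt$duration_s)

  fold <- integer(nrow(tt))
  fold[tt$condition == "task"] <- rep(seq_len(k), each = n_task / k)
  fold[tt$condition == "rest"] <- rep(seq_len(k), each = n_rest / k)

  n_correct_tp <- 0L
  n_total_tp <- 0L
  trial_correct <- logical(nrow(tt))
  latencies <- rep(NA_real_, nrow(tt))
  for (j in seq_len(k)) {
    train <- tt[fold != j, , drop = FALSE]
    test <- tt[fold == j, , drop = FALSE]
    fitted <- fit_model_on_trials(rec, train, model, wd, cost)
    pred <- if (model == "threshold") predict(fitted, rec) else
      predict(fitted, rec, trials = test)
    sc <- score_predictions(pred, test)
    n_correct_tp <- n_correct_tp + sc$n_correct
    n_total_tp <- n_total_tp + sc$n_total
    rows <- which(fold == j)
    trial_correct[rows] <- sc$by_trial$majority_correct
    if (model != "window") {
      for (m in seq_along(rows)) {
        if (test$condition[m] == "task") {
          latencies[rows[m]] <- detect_onset(pred, test$onset_s[m],
                                             test$duration_s[m], persistence)
        }
      }
    }
  }
  structure(list(model = model, k = k,
                 accuracy = n_correct_tp / n_total_tp,
                 n_correct = sum(trial_correct), n_trials = nrow(tt),
                 trial_correct = trial_correct, fold = fold,
                 latencies = latencies[tt$condition == "task"],
                 conditions = tt$condition),
            class = "cv_result")
}

#' Group statistics of per-participant accuracies against chance
#'
#' One-sample, one-tailed ("greater") t-test of the participant accuracies
#' against the chance level, the test used to declare a model's group
#' performance above chance (its 0.05 critical value at 39 degrees of freedom
#' is 1.68). A zero-variance sample is handled explicitly: `t = 0, p = 0.5`
#' when the mean equals chance, otherwise `t = +/-Inf` with `p = 0` or `1`.
#'
#' @param accuracies Numeric vector of per-participant accuracy fractions
#'   (length >= 2).
#' @param chance Chance level (default 0.5).
#' @param alpha Significance level used for the reported critical value.
#' @return List with `n`, `mean`, `sd`, `df`, `t`, `p`, `t_crit`,
#'   `significant`.
#' @export
group_stats <- function(accuracies, chance = 0.5, alpha = 0.05) {
  accuracies <- accuracies[!is.na(accuracies)]
  n <- length(accuracies)
  if (n < 2) stop("need accuracies from at least two participants",
                  call. = FALSE)
  m <- mean(accuracies)
  s <- stats::sd(accuracies)
  df <- n - 1
  if (s == 0) {
    t_obs <- if (m == chance) 0 else sign(m - chance) * Inf
  } else {
    t_obs <- (m - chance) / (s / sqrt(n))
  }
  p <- stats::pt(t_obs, df, lower.tail = FALSE)
  t_crit <- stats::qt(1 - alpha, df)
  list(n = n, mean = m, sd = s, df = df, t = t_obs, p = p, t_crit = t_crit,
       significant = p < alpha)
}

#' Exact binomial test of one participant's trial-level performance
#'
#' One-tailed ("greater") exact binomial test of `n_correct` successes in
#' `n_total` trials against the chance rate. Trial-level outcomes (majority
#' vote within each trial) are used rather than raw timepoints, which are
#' strongly autocorrelated and would make a timepoint-level binomial test
#' anticonservative.
#'
#' @param n_correct,n_total Correct and total trial counts.
#' @param chance Chance success probability.
#' @param alpha Significance level.
#' @return List with `p` and `significant`.
#' @export
per_participant_significance <- function(n_correct, n_total, chance = 0.5,
                                         alpha = 0.05) {
  if (!is_scalar_count(n_correct) || !is_scalar_count(n_total) ||
      n_total < 1) {
    stop("`n_correct` and `n_total` must be counts with n_total >= 1",
         call. = FALSE)
  }
  if (n_correct > n_total) {
    stop("`n_correct` cannot exceed `n_total`", call. = FALSE)
  }
  p <- stats::binom.test(n_correct, n_total, p = chance,
                         alternative = "greater")$p.value
  list(p = p, significant = p < alpha)
}

#' Paired comparison of two models' per-participant accuracies
#'
#' Two-tailed paired t-test on the accuracy differences of the same
#' participants in the same order. Zero-variance differences are handled
#' explicitly (`t = 0, p = 1` for identical reports; otherwise `t = +/-Inf`,
#' `p = 0`).
#'
#' @param acc_a,acc_b Equal-length numeric vectors of per-participant
#'   accuracies.
#' @return List with `n`, `mean_diff`, `t`, `df`, `p`.
#' @export
compare_models <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) {
    stop("accuracy vectors must pair the same participants", call. = FALSE)
  }
  keep <- !is.na(acc_a) & !is.na(acc_b)
  d <- acc_a[keep] - acc_b[keep]
  n <- length(d)
  if (n < 2) stop("need at least two paired accuracies", call. = FALSE)
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    t_obs <- if (abs(mean(d)) <= 1e-12) 0 else sign(mean(d)) * Inf
    p <- if (abs(mean(d)) <= 1e-12) 1 else 0
  } else {
    tst <- stats::t.test(d)
    t_obs <- unname(tst$statistic)
    p <- tst$p.value
  }
  list(n = n, mean_diff = mean(d), t = t_obs, df = n - 1, p = p)
}

#' Evaluate trained models on a continuous (realistic) recording
#'
#' Scores each fitted model's timepoint labels against the block labels of a
#' continuous paradigm (e.g. 3.5 min rest, 3.5 min task, 3.5 min post-task
#' rest). Threshold and pointwise models label every sample; window models
#' slide a window (stride `stride` seconds) and label causally from the first
#' complete window onward, so their accuracy is computed over the labelled
#' samples only. The onset-detection latency for the task segment is reported
#' per model, along with the majority-class baseline accuracy.
#'
#' @param rec A preprocessed [hemo_recording()].
#' @param trials The continuous paradigm's [trial_table()].
#' @param models Named list of fitted models (any mix of `threshold_model` and
#'   `workload_svm`).
#' @param stride Sliding-window stride in seconds.
#' @param persistence Consecutive-sample requirement for [detect_onset()].
#' @return A data frame with one row per model: `model`, `accuracy`,
#'   `n_correct`, `n_total`, `latency_s`, `majority_baseline`.
#' @export
evaluate_realistic <- function(rec, trials, models, stride = 1,
                               persistence = 1L) {
  stopifnot(inherits(rec, "hemo_recording"))
  validate_trial_table(trials)
  tt <- nonfixation_trials(trials)
  task_rows <- tt[tt$condition == "task", , drop = FALSE]
  # majority-class baseline: scored-sample fraction of the larger class
  counts <- vapply(c("rest", "task"), function(cond) {
    sum(vapply(which(tt$condition == cond), function(i) {
      length(trial_sample_index(rec, tt$onset_s[i], tt$duration_s[i]))
    }, numeric(1)))
  }, numeric(1))
  majority <- max(counts) / sum(counts)
  rows <- lapply(names(models), function(nm) {
    mdl <- models[[nm]]
    pred <- if (inherits(mdl, "workload_svm") && mdl$kind == "window") {
      predict(mdl, rec, trials = NULL, stride = stride)
    } else {
      predict(mdl, rec)
    }
    sc <- score_predictions(pred, tt)
    lat <- if (nrow(task_rows) > 0) {
      detect_onset(pred, task_rows$onset_s[1], task_rows$duration_s[1],
                   persistence)
    } else NA_real_
    data.frame(model = nm, accuracy = sc$accuracy, n_correct = sc$n_correct,
               n_total = sc$n_total, latency_s = lat,
               majority_baseline = majority, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summary statistics of per-participant onset latencies
#'
#' @param latencies Numeric vector of per-participant mean latencies in
#'   seconds; `NA` entries (participants with no detection) are counted and
#'   excluded.
#' @return List with `mean`, `sd`, `min`, `max`, `n`, `n_none`.
#' @export
latency_stats <- function(latencies) {
  n_none <- sum(is.na(latencies))
  lat <- latencies[!is.na(latencies)]
  if (length(lat) == 0) {
    stop("all latencies are missing (no detections)", call. = FALSE)
  }
  list(mean = mean(lat), sd = if (length(lat) > 1) stats::sd(lat) else
    NA_real_, min = min(lat), max = max(lat), n = length(lat),
    n_none = n_none)
}
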