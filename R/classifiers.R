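# The three compared workload models under a uniform fit/predict contract:
# reference-channel thresholding, per-timepoint 4-feature SVM, and
# full-timecourse window SVM; plus onset-latency detection.

#' Left-minus-right oxyhemoglobin difference series
#'
#' The reference-channel construction: the HbO series of a reference channel
#' is subtracted elementwise from the target channel's HbO series, cancelling
#' global (task-unrelated) activity common to both.
#'
#' @param rec A [hemo_recording()].
#' @param target,reference Distinct channel labels (default left / right).
#' @return Numeric series in micromolar.
#' @export
diff_series <- function(rec, target = "L", reference = "R") {
  stopifnot(inherits(rec, "hemo_recording"))
  if (identical(target, reference)) {
    stop("`target` and `reference` channels must differ", call. = FALSE)
  }
  chrom_series(rec, target, "HbO") - chrom_series(rec, reference, "HbO")
}

#' Fit the reference-channel thresholding model
#'
#' The decision threshold ("baseline") is, by default, the mean over rest
#' trials of the within-trial maximum of the left-minus-right HbO difference.
#' The training description this implements is ambiguous between a per-trial
#' and a whole-block maximum, so `baseline_stat = "block_max"` (maximum of the
#' difference over all rest samples) is available as an alternative.
#'
#' @param rec A preprocessed [hemo_recording()].
#' @param trials A [trial_table()] containing at least one rest trial.
#' @param target,reference Channel labels, as in [diff_series()].
#' @param baseline_stat `"mean_of_trial_max"` (default) or `"block_max"`.
#' @return An object of class `threshold_model` with fields `baseline`,
#'   `target`, `reference`.
#' @export
fit_threshold <- function(rec, trials, target = "L", reference = "R",
                          baseline_stat = c("mean_of_trial_max",
                                            "block_max")) {
  baseline_stat <- match.arg(baseline_stat)
  validate_trial_table(trials)
  rest <- trials[trials$condition == "rest", , drop = FALSE]
  if (nrow(rest) == 0) {
    stop("cannot fit threshold model: no rest trials", call. = FALSE)
  }
  d <- diff_series(rec, target, reference)
  maxima <- vapply(seq_len(nrow(rest)), function(i) {
    idx <- trial_sample_index(rec, rest$onset_s[i], rest$duration_s[i])
    max(d[idx])
  }, numeric(1))
  baseline <- if (baseline_stat == "mean_of_trial_max") mean(maxima) else
    max(maxima)
  structure(list(baseline = baseline, target = target, reference = reference,
                 baseline_stat = baseline_stat),
            class = "threshold_model")
}

#' Predict workload state with a threshold model
#'
#' Labels a timepoint `"task"` when the target-minus-reference HbO difference
#' strictly exceeds the fitted baseline ("exceeds" implies a strict
#' inequality; ties are labelled `"rest"`), `"rest"` otherwise. Every sample
#' of the recording receives a label.
#'
#' @param object A `threshold_model`.
#' @param rec A [hemo_recording()].
#' @param ... Unused.
#' @return A `prediction_series`: data frame with columns `time` (seconds) and
#'   `label` (factor, levels `rest`/`task`).
#' @export
predict.threshold_model <- function(object, rec, ...) {
  d <- diff_series(rec, object$target, object$reference)
  prediction_series(rec$time, ifelse(d > object$baseline, "task", "rest"))
}

prediction_series <- function(time, label) {
  if (is.unsorted(time, strictly = TRUE)) {
    stop("prediction timestamps must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(time = time,
                       label = factor(label, levels = c("rest", "task"))),
            class = c("prediction_series", "data.frame"))
}

#' Onset-detection latency of a prediction series
#'
#' The delay between a trial's onset and the classifier's first task-positive
#' output within the trial: the time of the first sample at or after the
#' onset labelled `"task"` (for `persistence > 1`, the first sample opening a
#' run of that many consecutive task labels), minus the onset.
#'
#' @param pred A `prediction_series`.
#' @param onset,duration Trial span in seconds (half-open
#'   `[onset, onset + duration)`).
#' @param persistence Number of consecutive task labels required (default 1).
#' @return Latency in seconds, or `NA_real_` when the trial contains no
#'   task-labelled sample.
#' @export
detect_onset <- function(pred, onset, duration, persistence = 1L) {
  stop_if_not_scalar_number(onset, "onset")
  stop_if_not_scalar_number(duration, "duration", positive = TRUE)
  if (!is_scalar_count(persistence) || persistence < 1) {
    stop("`persistence` must be a positive integer", call. = FALSE)
  }
  idx <- which(pred$time >= onset - 1e-9 & pred$time < onset + duration - 1e-9)
  if (length(idx) == 0) {
    stop("trial span lies outside the prediction range", call. = FALSE)
  }
  is_task <- pred$label[idx] == "task"
  if (persistence > 1L) {
    run <- stats::filter(as.numeric(is_task), rep(1, persistence),
                         sides = 1)
    first <- which(run == persistence)[1] - persistence + 1L
  } else {
    first <- which(is_task)[1]
  }
  if (is.na(first)) return(NA_real_)
  pred$time[idx[first]] - onset
}

# Index of the samples forming a trial: the first floor(duration * rate)
# samples starting at the first sample at or after the onset (half-open span,
# floor convention).
trial_sample_index <- function(rec, onset, duration) {
  i0 <- sample_at_or_after(onset, rec$rate)
  n_in <- samples_in_span(duration, rec$rate)
  if (n_in < 1L) stop("trial shorter than one sample", call. = FALSE)
  idx <- i0:(i0 + n_in - 1L)
  if (i0 < 1L || idx[n_in] > n_samples(rec)) {
    stop("trial span exceeds the recording", call. = FALSE)
  }
  idx
}

#' Per-timepoint feature matrix
#'
#' One row per sample falling inside a task or rest trial (fixation periods
#' are excluded), with the instantaneous amplitudes of all channels'
#' chromophores as features, in channel-major order (for the default
#' two-channel geometry: `L_HbO`, `L_Hb`, `R_HbO`, `R_Hb`).
#'
#' @param rec A preprocessed [hemo_recording()].
#' @param trials A [trial_table()].
#' @return A `labeled_samples` object: list with `design` (matrix), `labels`
#'   (factor `rest`/`task`) and `meta` (data frame with trial index and
#'   sample time).
#' @export
featurize_pointwise <- function(rec, trials) {
  stopifnot(inherits(rec, "hemo_recording"))
  validate_trial_table(trials)
  tt <- nonfixation_trials(trials)
  rows <- vector("list", nrow(tt))
  for (i in seq_len(nrow(tt))) {
    idx <- trial_sample_index(rec, tt$onset_s[i], tt$duration_s[i])
    rows[[i]] <- data.frame(trial = i, idx = idx,
                            condition = tt$condition[i])
  }
  meta <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(trial = integer(), idx = integer(), condition = character())
  design <- rec$data[meta$idx, , drop = FALSE]
  structure(list(design = design,
                 labels = factor(meta$condition, levels = c("rest", "task")),
                 meta = data.frame(trial = meta$trial,
                                   time = rec$time[meta$idx])),
            class = "labeled_samples")
}

#' Full-timecourse (window) feature matrix
#'
#' One row per task/rest trial: every chromophore series of every channel over
#' the first `window_duration` seconds of the trial, concatenated in
#' channel-major, chromophore, time order. Row length is
#' `floor(window_duration * rate) * 2 * n_channels`.
#'
#' @param rec A preprocessed [hemo_recording()].
#' @param trials A [trial_table()].
#' @param window_duration Window length in seconds (> 0). Trials shorter than
#'   the window raise an error unless `short_trials = "truncate"`, which
#'   shrinks the window to the shortest trial (silent padding would fabricate
#'   data).
#' @param short_trials `"error"` (default) or `"truncate"`.
#' @return A `labeled_samples` object; the realized window duration is stored
#'   in attribute `window_duration`.
#' @export
featurize_window <- function(rec, trials, window_duration,
                             short_trials = c("error", "truncate")) {
  stopifnot(inherits(rec, "hemo_recording"))
  short_trials <- match.arg(short_trials)
  stop_if_not_scalar_number(window_duration, "window_duration",
                            positive = TRUE)
  validate_trial_table(trials)
  tt <- nonfixation_trials(trials)
  if (nrow(tt) > 0 && min(tt$duration_s) < window_duration) {
    if (short_trials == "error") {
      stop(sprintf(
        "trial(s) shorter than the %g s window; use short_trials = \"truncate\" to shrink the window",
        window_duration), call. = FALSE)
    }
    window_duration <- min(tt$duration_s)
  }
  n_w <- samples_in_span(window_duration, rec$rate)
  if (n_w < 1L) stop("window shorter than one sample", call. = FALSE)
  cols <- as.vector(t(outer(rec$channels, c("HbO", "Hb"), paste, sep = "_")))
  design <- matrix(0, nrow = nrow(tt), ncol = n_w * length(cols))
  for (i in seq_len(nrow(tt))) {
    idx <- trial_sample_index(rec, tt$onset_s[i], tt$duration_s[i])[1:n_w]
    design[i, ] <- as.vector(rec$data[idx, cols])
  }
  colnames(design) <- paste0(rep(cols, each = n_w), "_t",
                             rep(seq_len(n_w), times = length(cols)))
  structure(list(design = design,
                 labels = factor(tt$condition, levels = c("rest", "task")),
                 meta = data.frame(trial = seq_len(nrow(tt)),
                                   time = tt$onset_s)),
            class = "labeled_samples",
            window_duration = window_duration)
}

#' Fit a linear support vector machine on labeled samples
#'
#' A soft-margin linear-kernel SVM with cost `C = 1` (solved by the SMO-type
#' optimizer in libsvm via \pkg{e1071}), fitted on per-feature standardized
#' inputs; standardization parameters are estimated from the training rows
#' only and stored in the model. Deterministic given fixed inputs.
#'
#' @param samples A `labeled_samples` object from [featurize_pointwise()] or
#'   [featurize_window()]; both classes must be present.
#' @param kind `"pointwise"` or `"window"`; recorded in the model and used to
#'   choose the featurization at prediction time.
#' @param cost Soft-margin cost parameter (default 1).
#' @param standardize Standardize features (default TRUE)?
#' @return An object of class `workload_svm`.
#' @export
fit_svm <- function(samples, kind = c("pointwise", "window"), cost = 1,
                    standardize = TRUE) {
  kind <- match.arg(kind)
  stopifnot(inherits(samples, "labeled_samples"))
  y <- droplevels(samples$labels)
  if (nlevels(y) < 2L) {
    stop("both classes (task and rest) must be present for fitting",
         call. = FALSE)
  }
  if (nrow(samples$design) < 2L) {
    stop("need at least two training rows", call. = FALSE)
  }
  x <- samples$design
  if (standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  } else {
    center <- rep(0, ncol(x))
    scale_ <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale_, "/")
  fit <- e1071::svm(xs, factor(y, levels = c("rest", "task")),
                    kernel = "linear", cost = cost, scale = FALSE)
  structure(list(kind = kind, fit = fit, center = center, scale = scale_,
                 n_features = ncol(x),
                 feature_names = colnames(x),
                 window_duration = attr(samples, "window_duration")),
            class = "workload_svm")
}

#' Predict workload state with a fitted SVM
#'
#' Pointwise models label every in-trial sample (or, with `trials = NULL`,
#' every sample of the recording). Window models label one window per trial
#' when `trials` is supplied; on continuous data (`trials = NULL`) they slide
#' a window with stride `stride` seconds, assigning each window's label to its
#' final timestamp (causal labelling).
#'
#' @param object A `workload_svm`.
#' @param rec A [hemo_recording()] with the geometry the model was trained on.
#' @param trials Optional [trial_table()].
#' @param stride Sliding-window stride in seconds (window models on
#'   continuous data).
#' @param ... Unused.
#' @return A `prediction_series`.
#' @export
predict.workload_svm <- function(object, rec, trials = NULL, stride = 1,
                                 ...) {
  stopifnot(inherits(rec, "hemo_recording"))
  if (object$kind == "pointwise") {
    if (is.null(trials)) {
      design <- rec$data
      time <- rec$time
    } else {
      s <- featurize_pointwise(rec, trials)
      design <- s$design
      time <- s$meta$time
    }
  } else {
    if (!is.null(trials)) {
      s <- featurize_window(rec, trials, object$window_duration)
      design <- s$design
      time <- s$meta$time
    } else {
      n_w <- samples_in_span(object$window_duration, rec$rate)
      step <- max(1L, as.integer(round(stride * rec$rate)))
      ends <- seq(n_w, n_samples(rec), by = step)
      if (length(ends) == 0) {
        stop("recording shorter than the model window", call. = FALSE)
      }
      cols <- as.vector(t(outer(rec$channels, c("HbO", "Hb"), paste,
                                sep = "_")))
      design <- t(vapply(ends, function(e) {
        as.vector(rec$data[(e - n_w + 1L):e, cols])
      }, numeric(n_w * length(cols))))
      time <- rec$time[ends]
    }
  }
  if (ncol(design) != object$n_features) {
    stop(sprintf(
      "feature dimension mismatch: model expects %d features, recording yields %d",
      object$n_features, ncol(design)), call. = FALSE)
  }
  if (nrow(design) == 0) {
    return(prediction_series(numeric(0), character(0)))
  }
  xs <- sweep(sweep(design, 2, object$center, "-"), 2, object$scale, "/")
  colnames(xs) <- colnames(object$fit$SV)
  lab <- as.character(predict(object$fit, xs))
  prediction_series(time, lab)
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf(
    "<threshold_model> task when %s_HbO - %s_HbO > %.4g uM (baseline: %s)\n",
    x$target, x$reference, x$baseline, x$baseline_stat))
  invisible(x)
}

#' @export
print.workload_svm <- function(x, ...) {
  cat(sprintf("<workload_svm> %s, %d features, linear kernel (C = %g)\n",
              x$kind, x$n_features, x$fit$cost))
  invisible(x)
}
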