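# Synthetic participant generator: ground-truth hemodynamics, physiological
# noise, and motion artifacts with the statistical structure the downstream
# models assume (anticorrelated HbO/Hb, common-mode artifacts, lateralized
# task response).

sinusoid <- function(time, freq, amplitude) {
  if (amplitude == 0) return(numeric(length(time)))
  phase <- stats::runif(1, 0, 2 * pi)
  amplitude * sin(2 * pi * freq * time + phase)
}

# Gaussian random walk low-passed below `cutoff`, rescaled to sd `amplitude`.
drift_series <- function(n, rate, cutoff, amplitude) {
  if (amplitude == 0) return(numeric(n))
  rw <- cumsum(stats::rnorm(n))
  W <- sg_window_for_cutoff(cutoff, rate, degree = 1,
                            max_window = min(2L * n - 1L, 4001L))
  slow <- sg_lowpass(rw, W, degree = 1)
  s <- stats::sd(slow)
  if (s == 0) return(numeric(n))
  (slow - mean(slow)) / s * amplitude
}

# Task-unrelated spontaneous hemodynamic events: kernel-shaped transients at
# Poisson times with lognormal peak amplitudes. Returned as an HbO-scale
# series; callers add `hb_ratio` times the same series to Hb, preserving the
# anticorrelation of genuine hemodynamics.
spontaneous_series <- function(n, rate, spont, hdr) {
  if (spont[1] == 0 || spont[2] == 0) return(numeric(n))
  out <- numeric(n)
  dur_min <- n / rate / 60
  n_ev <- stats::rpois(1, spont[1] * dur_min)
  if (n_ev == 0) return(out)
  at <- sort(stats::runif(n_ev, -10, n / rate)) # events may start pre-block
  amp <- spont[2] * stats::rlnorm(n_ev, 0, 0.5)
  k <- hdr_kernel(hdr, rate)
  for (j in seq_len(n_ev)) {
    i0 <- sample_at_or_after(at[j], rate)
    ks <- 1L
    if (i0 < 1L) {
      ks <- 2L - i0
      i0 <- 1L
    }
    len <- min(length(k) - ks + 1L, n - i0 + 1L)
    if (len < 1L) next
    idx <- i0:(i0 + len - 1L)
    out[idx] <- out[idx] + amp[j] * k[ks:(ks + len - 1L)]
  }
  out
}

# Poisson-process motion artifact series (spikes + baseline shifts).
motion_series <- function(n, rate, motion) {
  art <- numeric(n)
  dur_min <- n / rate / 60
  add_events <- function(art, rate_per_min, amplitude, shape) {
    if (rate_per_min == 0 || amplitude == 0) return(art)
    n_ev <- stats::rpois(1, rate_per_min * dur_min)
    if (n_ev == 0) return(art)
    at <- sort(stats::runif(n_ev, 0, n / rate))
    amp <- amplitude * stats::runif(n_ev, 0.5, 1.5) *
      sample(c(-1, 1), n_ev, replace = TRUE)
    for (j in seq_len(n_ev)) {
      i0 <- sample_at_or_after(at[j], rate)
      if (i0 > n) next
      idx <- i0:n
      if (shape == "spike") {
        tau <- 0.5 # seconds; decay constant of a sensor-slip transient
        art[idx] <- art[idx] + amp[j] * exp(-((idx - i0) / rate) / tau)
      } else {
        art[idx] <- art[idx] + amp[j]
      }
    }
    art
  }
  art <- add_events(art, motion$spike_rate, motion$spike_amplitude, "spike")
  art <- add_events(art, motion$shift_rate, motion$shift_amplitude, "shift")
  art
}

simulate_block <- function(trials, hdr, noise, motion, rate, channels) {
  validate_trial_table(trials)
  span <- trial_span(trials)
  n <- as.integer(ceiling(span * rate))
  time <- (seq_len(n) - 1L) / rate

  # weighted task boxcar: per-trial lognormal gain and uniform onset delay
  # model trial-to-trial response variability (drawn from the block's seeded
  # RNG stream before any noise draws)
  boxcar <- numeric(n)
  tasks <- trials[trials$condition == "task", , drop = FALSE]
  if (nrow(tasks) > 0) {
    # mean-one lognormal so hbo_amplitude stays the mean response amplitude
    gains <- if (hdr$trial_gain_sdlog > 0) {
      stats::rlnorm(nrow(tasks), -hdr$trial_gain_sdlog^2 / 2,
                    hdr$trial_gain_sdlog)
    } else rep(1, nrow(tasks))
    delays <- if (hdr$trial_onset_jitter > 0) {
      stats::runif(nrow(tasks), 0, hdr$trial_onset_jitter)
    } else rep(0, nrow(tasks))
    for (i in seq_len(nrow(tasks))) {
      sel <- time >= tasks$onset_s[i] + delays[i] - 1e-9 &
        time < tasks$onset_s[i] + tasks$duration_s[i] - 1e-9
      boxcar[sel] <- gains[i]
    }
  }
  response <- if (any(boxcar > 0)) hdr_response(boxcar, hdr, rate) else
    numeric(n)

  # response gain per channel: full amplitude left, (1 - lateralization) right;
  # channels beyond the first two get the right-channel gain
  gains <- c(1, rep(1 - hdr$lateralization, max(0L, length(channels) - 1L)))

  hb_ratio <- hdr$hb_to_hbo_ratio
  data <- matrix(0, nrow = n, ncol = 2L * length(channels))
  truth <- matrix(0, nrow = n, ncol = 2L * length(channels))
  cn <- as.vector(t(outer(channels, c("HbO", "Hb"), paste, sep = "_")))
  colnames(data) <- colnames(truth) <- cn

  for (i in seq_along(channels)) {
    hbo_true <- gains[i] * response
    hb_true <- hb_ratio * hbo_true
    truth[, 2L * i - 1L] <- hbo_true
    truth[, 2L * i] <- hb_true
    spont <- spontaneous_series(n, rate, noise$spontaneous, hdr)
    series <- list(HbO = hbo_true + spont, Hb = hb_true + hb_ratio * spont)
    scale_by <- c(HbO = 1, Hb = abs(hb_ratio))
    for (chrom in c("HbO", "Hb")) {
      s <- scale_by[[chrom]]
      x <- series[[chrom]] +
        sinusoid(time, noise$cardiac[1], s * noise$cardiac[2]) +
        sinusoid(time, noise$respiration[1], s * noise$respiration[2]) +
        sinusoid(time, noise$mayer[1], s * noise$mayer[2]) +
        drift_series(n, rate, noise$drift[1], s * noise$drift[2])
      if (noise$white_sd > 0) {
        x <- x + stats::rnorm(n, sd = s * noise$white_sd)
      }
      series[[chrom]] <- x
    }
    if (motion$common_mode) {
      art <- motion_series(n, rate, motion)
      series$HbO <- series$HbO + art
      series$Hb <- series$Hb + art
    } else {
      series$HbO <- series$HbO + motion_series(n, rate, motion)
      series$Hb <- series$Hb + motion_series(n, rate, motion)
    }
    data[, 2L * i - 1L] <- series$HbO
    data[, 2L * i] <- series$Hb
  }
  list(recording = hemo_recording(data, rate = rate, provenance = list(
    list(step = "simulate", block = trials$block[1]))),
    truth = truth)
}

#' Generate a synthetic participant dataset
#'
#' Simulates, for each block paradigm, a multichannel HbO/Hb recording: the
#' task boxcar convolved with the hemodynamic response kernel (scaled by
#' `hbo_amplitude` and the channel lateralization, with Hb a negative scalar
#' multiple of HbO, and per-trial gain/onset variability per [hdr_params()]),
#' plus seeded physiological noise (cardiac, respiratory and Mayer-wave
#' sinusoids with random phase, low-passed random-walk drift, white noise,
#' and task-unrelated spontaneous hemodynamic events) and Poisson motion
#' artifacts per [motion_params()]. The noise-free task-evoked series are
#' retained as ground truth.
#'
#' @param paradigms Named list of [trial_table()]s, one per block (e.g.
#'   `list(restricted = ..., unrestricted = ...)`). Names must be unique.
#' @param hdr An [hdr_params()] object.
#' @param noise A [noise_params()] object.
#' @param motion_by_block Named list of [motion_params()], one entry per block
#'   (defaults to no motion for a block named `"restricted"` and
#'   [motion_params()] defaults otherwise).
#' @param rate Sampling rate (Hz).
#' @param seed Integer seed; identical seeds and parameters yield
#'   bit-identical datasets.
#' @param channels Channel labels; the first is the (left) target channel
#'   carrying the lateralized response.
#' @param optics Optional [optics_params()]; when supplied, forward-modeled
#'   [optical_recording()]s are attached alongside the hemoglobin recordings.
#' @return An object of class `participant_dataset`: lists `recordings`,
#'   `truth`, `trials` (per block), optional `optical`, plus `seed` and the
#'   generating parameters.
#' @examples
#' tt <- generate_paradigm("training_block", n_task = 2, n_rest = 2,
#'                         trial_dur = 10, fixation_dur = 10, seed = 1)
#' ds <- generate_participant(list(restricted = tt), seed = 1)
#' ds$recordings$restricted
#' @export
generate_participant <- function(paradigms, hdr = hdr_params(),
                                 noise = noise_params(),
                                 motion_by_block = NULL, rate = 6.25,
                                 seed = 1L, channels = c("L", "R"),
                                 optics = NULL) {
  if (!is.list(paradigms) || length(paradigms) == 0 ||
      is.null(names(paradigms)) || any(names(paradigms) == "")) {
    stop("`paradigms` must be a non-empty named list of trial tables",
         call. = FALSE)
  }
  if (anyDuplicated(names(paradigms))) {
    stop("duplicate block names in `paradigms`", call. = FALSE)
  }
  stopifnot(inherits(hdr, "hdr_params"), inherits(noise, "noise_params"))
  stop_if_not_scalar_number(rate, "rate", positive = TRUE)
  blocks <- names(paradigms)
  if (is.null(motion_by_block)) {
    motion_by_block <- lapply(blocks, function(b) {
      if (b == "restricted") motion_none() else motion_params()
    })
    names(motion_by_block) <- blocks
  }
  missing_motion <- setdiff(blocks, names(motion_by_block))
  if (length(missing_motion) > 0) {
    stop("`motion_by_block` is missing block(s): ",
         paste(missing_motion, collapse = ", "), call. = FALSE)
  }

  out <- with_seed(seed, {
    res <- list(recordings = list(), truth = list(), optical = list())
    for (b in blocks) {
      sim <- simulate_block(paradigms[[b]], hdr, noise, motion_by_block[[b]],
                            rate, channels)
      res$recordings[[b]] <- sim$recording
      res$truth[[b]] <- sim$truth
      if (!is.null(optics)) {
        res$optical[[b]] <- forward_optics(sim$recording, optics)
      }
    }
    res
  })
  structure(list(recordings = out$recordings, truth = out$truth,
                 optical = if (!is.null(optics)) out$optical,
                 trials = paradigms, seed = seed,
                 params = list(hdr = hdr, noise = noise,
                               motion = motion_by_block, rate = rate,
                               channels = channels)),
            class = "participant_dataset")
}

#' @export
print.participant_dataset <- function(x, ...) {
  cat(sprintf("<participant_dataset> seed %d, blocks: %s\n", x$seed,
              paste(names(x$recordings), collapse = ", ")))
  invisible(x)
}
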