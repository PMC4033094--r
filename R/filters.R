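# Savitzky-Golay low-pass filtering (parameterized by cutoff frequency) and
# correlation-based motion-artifact correction.

.sg_cache <- new.env(parent = emptyenv())

# Central (steady-state) smoothing coefficients of a degree-p SG filter.
sg_smoother_coefs <- function(W, degree) {
  if (W %% 2 == 0 || W < degree + 2) {
    stop("SG window must be odd and exceed the polynomial degree + 1",
         call. = FALSE)
  }
  M <- signal::sgolay(p = degree, n = W)
  as.numeric(M[(W + 1) / 2, ])
}

# |H(f)| of the symmetric FIR smoother at normalized frequencies (cycles/sample).
sg_amplitude_response <- function(coefs, f_norm) {
  h <- (length(coefs) - 1L) / 2L
  j <- -h:h
  abs(as.numeric(cos(2 * pi * outer(f_norm, j)) %*% coefs))
}

#' Measured -3 dB frequency of a Savitzky-Golay smoother
#'
#' Evaluates the filter's amplitude response on a fine frequency grid and
#' locates (by linear interpolation) the first crossing of `1/sqrt(2)`.
#'
#' @param W Odd window length in samples.
#' @param degree Polynomial order.
#' @param rate Sampling rate (Hz).
#' @return The realized -3 dB frequency in Hz.
#' @export
sg_realized_cutoff <- function(W, degree, rate) {
  coefs <- sg_smoother_coefs(W, degree)
  f <- seq(0, 0.5, length.out = 4096L)
  amp <- sg_amplitude_response(coefs, f)
  target <- 1 / sqrt(2)
  below <- which(amp < target)
  if (length(below) == 0) return(rate / 2)
  i <- below[1]
  if (i == 1) return(0)
  # linear interpolation between the grid points straddling the crossing
  f_cross <- f[i - 1] + (f[i] - f[i - 1]) *
    (amp[i - 1] - target) / (amp[i - 1] - amp[i])
  f_cross * rate
}

#' Window length realizing a requested low-pass cutoff
#'
#' Savitzky-Golay filters are parameterized by window length, not cutoff
#' frequency. This selects the odd window length whose degree-`degree`
#' smoother has its measured -3 dB frequency closest to `cutoff`, searching
#' around the documented approximation
#' `f_c / rate ~ (degree + 1) / (3.2 W - 4.6)` and never returning fewer than
#' 5 samples. The realized -3 dB frequency (from the filter's frequency
#' response) is attached as attribute `realized_cutoff_hz`.
#'
#' @param cutoff Target -3 dB frequency (Hz); must lie below the Nyquist
#'   frequency `rate/2`.
#' @param rate Sampling rate (Hz).
#' @param degree Polynomial order (>= 1).
#' @param max_window Optional odd upper bound on the window length (used when
#'   a short series cannot support the ideal window).
#' @return Odd integer window length with attribute `realized_cutoff_hz`.
#' @examples
#' W <- sg_window_for_cutoff(0.15, 6.25, 1)
#' attr(W, "realized_cutoff_hz")
#' @export
sg_window_for_cutoff <- function(cutoff, rate, degree = 1,
                                 max_window = NULL) {
  stop_if_not_scalar_number(cutoff, "cutoff", positive = TRUE)
  stop_if_not_scalar_number(rate, "rate", positive = TRUE)
  if (cutoff >= rate / 2) {
    stop(sprintf("`cutoff` (%g Hz) must be below the Nyquist frequency %g Hz",
                 cutoff, rate / 2), call. = FALSE)
  }
  key <- paste(cutoff, rate, degree, max_window %||% "", sep = "|")
  if (!is.null(.sg_cache[[key]])) return(.sg_cache[[key]])

  as_odd <- function(w) {
    w <- as.integer(round(w))
    if (w %% 2L == 0L) w + 1L else w
  }
  w_min <- as_odd(max(5, degree + 2))
  fc_of <- function(W) sg_realized_cutoff(W, degree, rate)

  if (fc_of(w_min) <= cutoff) {
    best <- w_min
  } else {
    # bracket then bisect: realized cutoff decreases with window length
    lo <- w_min
    hi <- as_odd(max(w_min + 2, ((degree + 1) * rate / cutoff + 4.6) / 3.2))
    while (fc_of(hi) > cutoff && hi < 1e5) hi <- as_odd(2 * hi)
    while (hi - lo > 2L) {
      mid <- as_odd((lo + hi) / 2)
      if (mid <= lo) mid <- lo + 2L
      if (mid >= hi) mid <- hi - 2L
      if (fc_of(mid) > cutoff) lo <- mid else hi <- mid
    }
    best <- if (abs(fc_of(lo) - cutoff) <= abs(fc_of(hi) - cutoff)) lo else hi
  }
  if (!is.null(max_window) && best > max_window) {
    best <- as_odd(min(best, max_window))
    if (best %% 2L == 0L) best <- best - 1L
  }
  out <- structure(best, realized_cutoff_hz = fc_of(best))
  .sg_cache[[key]] <- out
  out
}

#' Zero-phase Savitzky-Golay low-pass of one series
#'
#' Applies the central SG smoothing coefficients as a symmetric FIR filter
#' with mirror padding of half a window at each end (avoiding edge ramps that
#' would leak into the first and last trials of a block).
#'
#' @param x Numeric series.
#' @param W Odd window length (samples); see [sg_window_for_cutoff()].
#' @param degree Polynomial order.
#' @return Filtered series, same length as `x`.
#' @export
sg_lowpass <- function(x, W, degree = 1) {
  n <- length(x)
  W <- as.integer(W)
  h <- (W - 1L) %/% 2L
  if (n < h + 1L) {
    stop(sprintf(
      "series too short for a %d-sample window: need at least %d samples",
      W, h + 1L), call. = FALSE)
  }
  coefs <- sg_smoother_coefs(W, degree)
  pad <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  y <- stats::filter(pad, coefs, method = "convolution", sides = 2)
  as.numeric(y[(h + 1L):(h + n)])
}

apply_per_series <- function(rec, fn) {
  out <- rec
  for (j in seq_len(ncol(rec$data))) out$data[, j] <- fn(rec$data[, j])
  out
}

#' Detrend a recording by low-pass subtraction
#'
#' Replaces each series `x` by `x - lowpass(x)`, where the low-pass is a
#' degree-`sg_degree` Savitzky-Golay filter with -3 dB point at
#' `settings$detrend_cut` (default 0.01 Hz), removing baseline drift.
#'
#' @param rec A [hemo_recording()].
#' @param settings A [filter_settings()] object.
#' @return The detrended recording; provenance gains a `"detrend"` entry with
#'   the realized cutoff.
#' @export
detrend <- function(rec, settings = filter_settings()) {
  stopifnot(inherits(rec, "hemo_recording"),
            inherits(settings, "filter_settings"))
  W <- sg_window_for_cutoff(settings$detrend_cut, rec$rate,
                            settings$sg_degree)
  min_n <- (W - 1L) %/% 2L + 1L
  if (n_samples(rec) < min_n) {
    stop(sprintf(
      "recording too short to detrend at %g Hz: need >= %.1f s (%d samples)",
      settings$detrend_cut, min_n / rec$rate, min_n), call. = FALSE)
  }
  out <- apply_per_series(rec, function(x) {
    x - sg_lowpass(x, W, settings$sg_degree)
  })
  add_provenance(out, "detrend", list(
    cutoff_hz = settings$detrend_cut, window = as.integer(W),
    degree = settings$sg_degree,
    realized_cutoff_hz = attr(W, "realized_cutoff_hz")))
}

#' Smooth a recording with a Savitzky-Golay low-pass
#'
#' Attenuates systemic physiological components (cardiac pulsation,
#' respiration) by low-pass filtering each series at `settings$smooth_cut`
#' (default 0.15 Hz).
#'
#' @inheritParams detrend
#' @return The smoothed recording; provenance gains a `"smooth"` entry.
#' @export
smooth_recording <- function(rec, settings = filter_settings()) {
  stopifnot(inherits(rec, "hemo_recording"),
            inherits(settings, "filter_settings"))
  W <- sg_window_for_cutoff(settings$smooth_cut, rec$rate, settings$sg_degree)
  min_n <- (W - 1L) %/% 2L + 1L
  if (n_samples(rec) < min_n) {
    stop(sprintf(
      "recording too short to smooth at %g Hz: need >= %.1f s (%d samples)",
      settings$smooth_cut, min_n / rec$rate, min_n), call. = FALSE)
  }
  out <- apply_per_series(rec, function(x) {
    sg_lowpass(x, W, settings$sg_degree)
  })
  add_provenance(out, "smooth", list(
    cutoff_hz = settings$smooth_cut, window = as.integer(W),
    degree = settings$sg_degree,
    realized_cutoff_hz = attr(W, "realized_cutoff_hz")))
}

#' Correlation-based signal improvement (CBSI)
#'
#' Motion correction exploiting two assumptions: the true HbO and Hb series
#' are perfectly anticorrelated, and motion artifacts are common mode (added
#' equally to both). With `alpha = sd(hbo) / sd(hb)` computed on the
#' mean-centered series, the corrected signals are
#' `hbo_c = (hbo - alpha * hb) / 2` and `hb_c = -hbo_c / alpha`, which are
#' exactly anticorrelated by construction.
#'
#' @param hbo,hb Numeric series of equal length (>= 2 samples); `hb` must have
#'   positive standard deviation.
#' @return A list with elements `hbo`, `hb` (corrected series) and `alpha`.
#' @references Cui, X., Bray, S., & Reiss, A. L. (2010). Functional near
#'   infrared spectroscopy (NIRS) signal improvement based on negative
#'   correlation between oxygenated and deoxygenated hemoglobin dynamics.
#'   NeuroImage, 49(4), 3039-3046.
#' @export
cbsi <- function(hbo, hb) {
  if (length(hbo) != length(hb)) {
    stop("`hbo` and `hb` must have equal length", call. = FALSE)
  }
  if (length(hbo) < 2L) stop("need at least 2 samples", call. = FALSE)
  sd_hb <- stats::sd(hb)
  if (!is.finite(sd_hb) || sd_hb == 0) {
    stop("sd(hb) is zero: CBSI scaling factor alpha is undefined",
         call. = FALSE)
  }
  x <- hbo - mean(hbo)
  y <- hb - mean(hb)
  alpha <- stats::sd(x) / sd_hb
  hbo_c <- (x - alpha * y) / 2
  list(hbo = hbo_c, hb = -hbo_c / alpha, alpha = alpha)
}

#' Full preprocessing chain
#'
#' Applies, in order: detrend (low-pass subtraction at `detrend_cut`), smooth
#' (low-pass at `smooth_cut`), then CBSI motion correction per channel
#' (pairing each channel's HbO with its own Hb; channels are never mixed).
#' Channels whose Hb series has zero variance skip CBSI with a warning rather
#' than failing the whole pipeline.
#'
#' @inheritParams detrend
#' @return The preprocessed recording with a complete provenance log.
#' @export
preprocess_pipeline <- function(rec, settings = filter_settings()) {
  out <- smooth_recording(detrend(rec, settings), settings)
  if (settings$cbsi_enabled) {
    alphas <- list()
    for (ch in out$channels) {
      hbo <- out$data[, paste0(ch, "_HbO")]
      hb <- out$data[, paste0(ch, "_Hb")]
      if (stats::sd(hb) == 0) {
        warning(sprintf(
          "channel %s: zero-variance Hb series, skipping CBSI", ch),
          call. = FALSE)
        next
      }
      corrected <- cbsi(hbo, hb)
      out$data[, paste0(ch, "_HbO")] <- corrected$hbo
      out$data[, paste0(ch, "_Hb")] <- corrected$hb
      alphas[[ch]] <- corrected$alpha
    }
    out <- add_provenance(out, "cbsi", list(alpha = alphas))
  }
  out
}
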