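#' Sampled hemodynamic response kernel
#'
#' Returns a unit-peak hemodynamic response kernel sampled at `rate` Hz. The
#' kernel is zero before `onset_lag`, rises as a single gamma-shaped lobe with
#' its maximum exactly `time_to_peak` seconds after the lag (to sample
#' precision), and decays back below 5% of the peak by the end of its support.
#' If `undershoot_fraction > 0`, a second gamma lobe peaking at twice
#' `time_to_peak` is subtracted before peak renormalization.
#'
#' The gamma lobe uses a fixed shape parameter of 6, i.e.
#' `g(u) = (u/tp)^5 * exp(5 * (1 - u/tp))` with `u` the time since response
#' onset and `tp = time_to_peak`, which is exactly 1 at `u = tp`.
#'
#' @param params An [hdr_params()] object (amplitude fields are ignored here;
#'   the kernel is unit peak).
#' @param rate Sampling rate in Hz (> 0).
#' @return Numeric vector of kernel samples with attribute `time` giving the
#'   sample times in seconds (starting at 0).
#' @examples
#' k <- hdr_kernel(hdr_params(onset_lag = 1.5, time_to_peak = 6), rate = 6.25)
#' attr(k, "time")[which.max(k)] # ~7.5 s
#' @export
hdr_kernel <- function(params, rate) {
  stopifnot(inherits(params, "hdr_params"))
  stop_if_not_scalar_number(rate, "rate", positive = TRUE)
  lag <- params$onset_lag
  tp <- params$time_to_peak
  us <- params$undershoot_fraction
  shape_k <- 6
  # main lobe is ~1% of peak at u = 3*tp; extend support when an undershoot
  # lobe (peaking at 2*tp) must also decay
  support <- lag + 3 * tp + if (us > 0) 3 * tp else 0
  n <- as.integer(ceiling(support * rate)) + 1L
  t <- (seq_len(n) - 1L) / rate
  u <- t - lag
  gamma_lobe <- function(u, mode) {
    v <- numeric(length(u))
    pos <- u > 0
    r <- u[pos] / mode
    v[pos] <- r^(shape_k - 1) * exp((shape_k - 1) * (1 - r))
    v
  }
  k <- gamma_lobe(u, tp)
  if (us > 0) k <- k - us * gamma_lobe(u, 2 * tp)
  k <- k / max(k)
  attr(k, "time") <- t
  k
}

#' Convolve a task boxcar with the hemodynamic response kernel
#'
#' Produces the noise-free HbO response (micromolar) for a block paradigm: the
#' task indicator is convolved with the unit-peak kernel and normalized by the
#' kernel sum, so a sustained task approaches `hbo_amplitude` at plateau.
#'
#' @param boxcar 0/1 task indicator, one value per sample.
#' @param params An [hdr_params()] object.
#' @param rate Sampling rate (Hz).
#' @return Numeric vector the same length as `boxcar`.
#' @export
hdr_response <- function(boxcar, params, rate) {
  k <- hdr_kernel(params, rate)
  n <- length(boxcar)
  # time-domain convolution keeps pre-stimulus samples exactly zero (an FFT
  # convolution would leave ~1e-15 wiggle that a strict threshold against a
  # zero baseline could cross)
  padded <- c(numeric(length(k) - 1L), boxcar)
  full <- stats::filter(padded, k, method = "convolution", sides = 1)
  as.numeric(full[length(k):(length(k) + n - 1L)]) / sum(k) *
    params$hbo_amplitude
}
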