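#' Construct a hemoglobin-concentration recording
#'
#' The central data container of the pipeline: per-channel timeseries of
#' oxygenated (HbO) and deoxygenated (Hb) hemoglobin concentration changes in
#' micromolar, sampled on a regular grid. Column names follow the pattern
#' `<channel>_HbO` / `<channel>_Hb` in channel-major order.
#'
#' @param data Numeric matrix (samples x series) with column names like
#'   `L_HbO`, `L_Hb`, `R_HbO`, `R_Hb`.
#' @param rate Sampling rate in Hz (> 0). Default 6.25 Hz, the temporal
#'   resolution of a typical frequency-domain two-channel instrument.
#' @param provenance List of processing-step records; each entry a list with
#'   at least a `step` name.
#' @return An object of class `hemo_recording` with fields `data`, `rate`,
#'   `time`, `channels`, `provenance`.
#' @export
hemo_recording <- function(data, rate = 6.25, provenance = list()) {
  stop_if_not_scalar_number(rate, "rate", positive = TRUE)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be numeric", call. = FALSE)
  cn <- colnames(data)
  if (is.null(cn) || !all(grepl("^.+_(HbO|Hb)$", cn))) {
    stop("columns must be named <channel>_HbO / <channel>_Hb", call. = FALSE)
  }
  channels <- unique(sub("_(HbO|Hb)$", "", cn))
  for (ch in channels) {
    for (chrom in c("HbO", "Hb")) {
      if (!paste(ch, chrom, sep = "_") %in% cn) {
        stop(sprintf("channel %s is missing its %s series", ch, chrom),
             call. = FALSE)
      }
    }
  }
  # canonical channel-major column order
  data <- data[, as.vector(t(outer(channels, c("HbO", "Hb"), paste,
                                   sep = "_"))), drop = FALSE]
  structure(list(data = data, rate = rate,
                 time = (seq_len(nrow(data)) - 1L) / rate,
                 channels = channels, provenance = provenance),
            class = "hemo_recording")
}

#' Construct a two-wavelength optical-density recording
#'
#' Stores per-channel optical-density changes at the instrument's two
#' wavelengths; produced by [forward_optics()] and consumed by
#' [mbll_invert()]. Column names follow `<channel>_OD<wavelength>`.
#'
#' @param data Numeric matrix (samples x series), columns `<channel>_OD<nm>`.
#' @param rate Sampling rate in Hz.
#' @param optics An [optics_params()] object describing wavelengths,
#'   extinction coefficients, source-detector separation and differential
#'   pathlength factors.
#' @param provenance Processing-step log.
#' @return An object of class `optical_recording`.
#' @export
optical_recording <- function(data, rate = 6.25, optics = optics_params(),
                              provenance = list()) {
  stop_if_not_scalar_number(rate, "rate", positive = TRUE)
  data <- as.matrix(data)
  cn <- colnames(data)
  if (is.null(cn) || !all(grepl("^.+_OD[0-9]+$", cn))) {
    stop("columns must be named <channel>_OD<wavelength_nm>", call. = FALSE)
  }
  wl <- sort(unique(as.numeric(sub("^.+_OD", "", cn))))
  if (length(wl) != 2L) {
    stop("an optical recording must have exactly two wavelengths",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(wl, sort(optics$wavelengths)))) {
    stop("column wavelengths do not match `optics$wavelengths`",
         call. = FALSE)
  }
  channels <- unique(sub("_OD[0-9]+$", "", cn))
  data <- data[, as.vector(t(outer(channels, paste0("OD", wl), paste,
                                   sep = "_"))), drop = FALSE]
  structure(list(data = data, rate = rate,
                 time = (seq_len(nrow(data)) - 1L) / rate,
                 channels = channels, wavelengths = wl, optics = optics,
                 provenance = provenance),
            class = "optical_recording")
}

#' Number of samples in a recording
#' @param rec A `hemo_recording` or `optical_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' Extract one chromophore series
#'
#' @param rec A `hemo_recording`.
#' @param channel Channel label.
#' @param chromophore `"HbO"` or `"Hb"`.
#' @return Numeric vector.
#' @export
chrom_series <- function(rec, channel, chromophore = c("HbO", "Hb")) {
  chromophore <- match.arg(chromophore)
  col <- paste(channel, chromophore, sep = "_")
  if (!col %in% colnames(rec$data)) {
    stop(sprintf("recording has no series `%s`", col), call. = FALSE)
  }
  rec$data[, col]
}

add_provenance <- function(rec, step, params = list()) {
  rec$provenance <- c(rec$provenance, list(c(list(step = step), params)))
  rec
}

#' @export
print.hemo_recording <- function(x, ...) {
  cat(sprintf("<hemo_recording> %d samples @ %.4g Hz (%.1f s), channels: %s\n",
              n_samples(x), x$rate, n_samples(x) / x$rate,
              paste(x$channels, collapse = ", ")))
  if (length(x$provenance) > 0) {
    cat("  processing:", paste(vapply(x$provenance, `[[`, "", "step"),
                               collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
print.optical_recording <- function(x, ...) {
  cat(sprintf(
    "<optical_recording> %d samples @ %.4g Hz, channels: %s, wavelengths: %s nm\n",
    n_samples(x), x$rate, paste(x$channels, collapse = ", "),
    paste(x$wavelengths, collapse = "/")))
  invisible(x)
}
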