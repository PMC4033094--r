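# TSV interchange for recordings and trial tables, with JSON provenance
# sidecars. TSV is the canonical format: human-diffable and test-friendly.

check_overwrite <- function(path, force) {
  if (file.exists(path) && !force) {
    stop(sprintf("`%s` exists; set force = TRUE to overwrite", path),
         call. = FALSE)
  }
  invisible(path)
}

provenance_sidecar_path <- function(path) paste0(path, ".prov.json")

write_provenance <- function(provenance, path) {
  jsonlite::write_json(
    list(software = paste0("nirsbci ",
                           as.character(utils::packageVersion("nirsbci"))),
         steps = provenance),
    provenance_sidecar_path(path), auto_unbox = TRUE, digits = NA,
    null = "null")
}

#' Write a recording to a TSV file
#'
#' Hemoglobin recordings are written as a `time_s` column plus one column per
#' channel-chromophore series (e.g. `L_HbO`); optical recordings use
#' `<channel>_OD<wavelength>` columns. A JSON provenance sidecar
#' (`<path>.prov.json`) listing the processing steps is written alongside.
#'
#' @param rec A [hemo_recording()] or [optical_recording()].
#' @param path Output file path.
#' @param force Overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, force = FALSE) {
  if (!inherits(rec, "hemo_recording") && !inherits(rec, "optical_recording")) {
    stop("`rec` must be a hemo_recording or optical_recording", call. = FALSE)
  }
  check_overwrite(path, force)
  df <- data.frame(time_s = rec$time, rec$data, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(rec$provenance, path)
  invisible(path)
}

#' Read a recording from a TSV file
#'
#' Detects the recording type from the column names: `<channel>_HbO`/`_Hb`
#' columns yield a [hemo_recording()]; `<channel>_OD<wavelength>` columns an
#' [optical_recording()] (supply `optics` to override the defaults inferred
#' from the column wavelengths). The sampling rate is inferred from the
#' median timestamp increment; non-monotone timestamps are an error.
#'
#' @param path TSV file with a `time_s` column.
#' @param optics Optional [optics_params()] for optical recordings.
#' @return A [hemo_recording()] or [optical_recording()].
#' @export
read_recording <- function(path, optics = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) {
    stop("missing required column `time_s`", call. = FALSE)
  }
  time <- df$time_s
  if (length(time) < 2 || any(diff(time) <= 0)) {
    stop("column `time_s` must be strictly increasing (non-monotone timestamps)",
         call. = FALSE)
  }
  rate <- 1 / stats::median(diff(time))
  series <- names(df)[names(df) != "time_s"]
  hemo_like <- grepl("^.+_(HbO|Hb)$", series)
  od_like <- grepl("^.+_OD[0-9]+$", series)
  if (all(hemo_like) && length(series) > 0) {
    hemo_recording(as.matrix(df[series]), rate = rate,
                   provenance = read_sidecar(path))
  } else if (all(od_like) && length(series) > 0) {
    wl <- sort(unique(as.numeric(sub("^.+_OD", "", series))))
    optics <- optics %||% optics_params(wavelengths = wl)
    optical_recording(as.matrix(df[series]), rate = rate, optics = optics,
                      provenance = read_sidecar(path))
  } else {
    bad <- series[!(hemo_like | od_like)]
    stop("unrecognized series column(s) (expected `<channel>_HbO`, `<channel>_Hb` or `<channel>_OD<nm>`): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

read_sidecar <- function(path) {
  sc <- provenance_sidecar_path(path)
  if (!file.exists(sc)) return(list())
  out <- tryCatch(jsonlite::read_json(sc), error = function(e) list())
  out$steps %||% list()
}

#' Write a trial table to TSV
#'
#' @param trials A [trial_table()].
#' @param path Output path.
#' @param force Overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, force = FALSE) {
  validate_trial_table(trials)
  check_overwrite(path, force)
  utils::write.table(as.data.frame(trials), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a trial table from TSV
#'
#' @param path TSV with columns `onset_s`, `duration_s`, `condition`, `block`.
#' @return A [trial_table()].
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(condition = "character",
                                         block = "character"))
  trial_table(df$onset_s, df$duration_s, df$condition, df$block)
}
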