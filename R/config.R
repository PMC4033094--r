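# YAML serialization of study configurations.

#' Write a study configuration to YAML
#'
#' @param config A [study_config()].
#' @param path Output path.
#' @param force Overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path, force = FALSE) {
  stopifnot(inherits(config, "study_config"))
  check_overwrite(path, force)
  plain <- lapply(unclass(config), function(x) {
    if (is.list(x)) unclass(x) else x
  })
  yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' The file must mirror the [study_config()] parameter structure and must
#' name a `seed`; every value is re-validated through the constructors, so
#' malformed entries fail with the offending name.
#'
#' @param path YAML file written by [write_study_config()] or by hand.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("config must name a `seed`", call. = FALSE)
  rebuild <- function(x, ctor) do.call(ctor, x)
  args <- raw
  for (nm in c("hdr", "noise", "filter")) {
    if (!is.null(args[[nm]])) {
      args[[nm]] <- rebuild(args[[nm]],
                            switch(nm, hdr = hdr_params,
                                   noise = noise_params,
                                   filter = filter_settings))
    }
  }
  for (nm in c("motion_restricted", "motion_unrestricted",
               "motion_realistic")) {
    if (!is.null(args[[nm]])) args[[nm]] <- rebuild(args[[nm]], motion_params)
  }
  known <- names(formals(study_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(study_config, args)
}
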