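# Deterministic miniature datasets used by the test suite and documentation.

#' Write a deterministic miniature dataset to disk
#'
#' Three named fixtures are available:
#' \describe{
#'   \item{`tiny_clean`}{two participants, a small training block (two task +
#'     two rest trials of 10 s, 10 s fixation), no noise and no motion --
#'     HbO/Hb are exactly anticorrelated.}
#'   \item{`tiny_motion`}{as `tiny_clean` but with frequent common-mode motion
#'     spikes, which push the HbO/Hb correlation towards +1.}
#'   \item{`realistic_demo`}{one participant, one continuous 630 s block
#'     (rest/task/rest, 210 s each) with default physiological noise.}
#' }
#' Regenerating a fixture with the same seed yields identical files.
#'
#' @param name One of `"tiny_clean"`, `"tiny_motion"`, `"realistic_demo"`.
#' @param dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param force Overwrite existing files?
#' @return Character vector of the written file paths, invisibly.
#' @export
make_fixture <- function(name = c("tiny_clean", "tiny_motion",
                                  "realistic_demo"),
                         dir, seed = 1L, force = FALSE) {
  name <- match.arg(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  emit <- function(ds, who) {
    out <- character(0)
    for (block in names(ds$recordings)) {
      rp <- file.path(dir, sprintf("%s_%s_%s.tsv", name, who, block))
      tp <- file.path(dir, sprintf("%s_%s_%s_trials.tsv", name, who, block))
      write_recording(ds$recordings[[block]], rp, force = force)
      write_trials(ds$trials[[block]], tp, force = force)
      out <- c(out, rp, tp)
    }
    out
  }
  if (name %in% c("tiny_clean", "tiny_motion")) {
    motion <- if (name == "tiny_motion") {
      motion_params(spike_rate = 20, spike_amplitude = 5, shift_rate = 2,
                    shift_amplitude = 2)
    } else {
      motion_none()
    }
    noise <- noise_none()
    for (p in 1:2) {
      tt <- generate_paradigm("training_block", n_task = 2, n_rest = 2,
                              trial_dur = 10, fixation_dur = 10,
                              seed = seed + p, block = "training")
      ds <- generate_participant(
        list(training = tt),
        hdr = hdr_params(lateralization = 0.6, trial_gain_sdlog = 0,
                         trial_onset_jitter = 0),
        noise = noise, motion_by_block = list(training = motion),
        seed = seed + 100L + p)
      paths <- c(paths, emit(ds, paste0("p", p)))
    }
  } else {
    tt <- generate_paradigm("realistic", block = "realistic")
    ds <- generate_participant(list(realistic = tt),
                               motion_by_block = list(realistic =
                                                        motion_none()),
                               seed = seed + 100L)
    paths <- c(paths, emit(ds, "p1"))
  }
  invisible(paths)
}
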