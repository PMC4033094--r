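# Shared builders for small in-memory recordings and paradigms.

withr_local_tempdir <- function(env = parent.frame()) {
  dir <- tempfile("nirsbci-test-")
  dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE), envir = env)
  dir
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

rec_from_columns <- function(..., rate = 6.25) {
  cols <- list(...)
  hemo_recording(do.call(cbind, cols), rate = rate)
}

# A two-channel recording with arbitrary L/R HbO series; Hb defaults to the
# negated HbO so CBSI-style assumptions hold.
two_channel_rec <- function(l_hbo, r_hbo = numeric(length(l_hbo)),
                            l_hb = -l_hbo / 3, r_hb = -r_hbo / 3,
                            rate = 6.25) {
  rec_from_columns(L_HbO = l_hbo, L_Hb = l_hb, R_HbO = r_hbo, R_Hb = r_hb,
                   rate = rate)
}

# Small noise-free participant: deterministic responses, no per-trial
# variability, ideal for exact-value tests.
clean_participant <- function(trials, lateralization = 1, seed = 1,
                              hbo_amplitude = 0.5) {
  generate_participant(
    list(b = trials),
    hdr = hdr_params(hbo_amplitude = hbo_amplitude,
                     lateralization = lateralization,
                     trial_gain_sdlog = 0, trial_onset_jitter = 0),
    noise = noise_none(),
    motion_by_block = list(b = motion_none()),
    seed = seed)
}

# Same sample-index convention as the package: first sample at/after onset,
# floor(duration * rate) samples.
trial_sample_index_for_test <- function(rec, onset, duration) {
  i0 <- as.integer(ceiling(onset * rec$rate - 1e-9)) + 1L
  n <- as.integer(floor(duration * rec$rate + 1e-9))
  i0:(i0 + n - 1L)
}

small_block <- function(seed = 1, n_task = 2, n_rest = 2, trial_dur = 10,
                        fixation_dur = 10) {
  generate_paradigm("training_block", n_task = n_task, n_rest = n_rest,
                    trial_dur = trial_dur, fixation_dur = fixation_dur,
                    seed = seed, block = "b")
}
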