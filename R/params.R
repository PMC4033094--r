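#' Hemodynamic response parameters
#'
#' Parameterizes the simulator's task-evoked hemodynamic response. The
#' response to a sustained task is modeled as the task boxcar convolved with a
#' unit-peak single-gamma kernel (see [hdr_kernel()]): the oxygenated
#' hemoglobin (HbO) response lags task onset by `onset_lag` seconds, peaks
#' `time_to_peak` seconds after the lag, and the deoxygenated hemoglobin (Hb)
#' response is an inverted, scaled copy of the HbO response.
#'
#' @param onset_lag Seconds between stimulus onset and the start of the
#'   hemodynamic response. Typical reported values are 1--2 s.
#' @param time_to_peak Seconds from response onset to the response peak, so
#'   the peak occurs `onset_lag + time_to_peak` seconds after stimulus onset.
#'   Typical reported values place the peak 4--8 s after stimulus onset.
#' @param undershoot_fraction Amplitude of a post-stimulus undershoot lobe
#'   relative to the main lobe (0 disables it; the default). When positive, a
#'   second gamma peaking at twice `time_to_peak` is subtracted.
#' @param hbo_amplitude Sustained-response amplitude of HbO in micromolar
#'   concentration change for a long task block.
#' @param hb_to_hbo_ratio Negative unitless scale mapping the HbO response to
#'   the Hb response (Hb decreases when HbO increases).
#' @param lateralization Fraction of the response carried by the left channel
#'   relative to the right, in \[0, 1\]. With 1 (the default) the response is
#'   fully left-lateralized, so the left-minus-right HbO difference used by
#'   the reference-channel thresholding model carries the whole response.
#' @param trial_gain_sdlog sdlog of a lognormal per-trial response gain
#'   (0 disables it). Single-trial evoked responses vary substantially from
#'   trial to trial (attention, effort, habituation); the default corresponds
#'   to a coefficient of variation around 50%.
#' @param trial_onset_jitter Maximum extra per-trial onset delay in seconds
#'   (uniform on `[0, trial_onset_jitter]`), modelling variable task
#'   engagement after the cue.
#' @return An object of class `hdr_params`.
#' @seealso [hdr_kernel()], [generate_participant()]
#' @export
hdr_params <- function(onset_lag = 1.5, time_to_peak = 6,
                       undershoot_fraction = 0, hbo_amplitude = 0.5,
                       hb_to_hbo_ratio = -1 / 3, lateralization = 1,
                       trial_gain_sdlog = 0.5, trial_onset_jitter = 1) {
  stop_if_not_scalar_number(onset_lag, "onset_lag")
  stop_if_not_scalar_number(time_to_peak, "time_to_peak", positive = TRUE)
  stop_if_not_scalar_number(undershoot_fraction, "undershoot_fraction")
  stop_if_not_scalar_number(hbo_amplitude, "hbo_amplitude")
  stop_if_not_scalar_number(hb_to_hbo_ratio, "hb_to_hbo_ratio")
  stop_if_not_scalar_number(lateralization, "lateralization")
  if (onset_lag < 0) stop("`onset_lag` must be >= 0", call. = FALSE)
  if (hb_to_hbo_ratio >= 0) {
    stop("`hb_to_hbo_ratio` must be negative (Hb response is inverted)",
         call. = FALSE)
  }
  if (undershoot_fraction < 0 || undershoot_fraction >= 1) {
    stop("`undershoot_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (lateralization < 0 || lateralization > 1) {
    stop("`lateralization` must be in [0, 1]", call. = FALSE)
  }
  stop_if_not_scalar_number(trial_gain_sdlog, "trial_gain_sdlog")
  stop_if_not_scalar_number(trial_onset_jitter, "trial_onset_jitter")
  if (trial_gain_sdlog < 0 || trial_onset_jitter < 0) {
    stop("`trial_gain_sdlog` and `trial_onset_jitter` must be >= 0",
         call. = FALSE)
  }
  structure(list(onset_lag = onset_lag, time_to_peak = time_to_peak,
                 undershoot_fraction = undershoot_fraction,
                 hbo_amplitude = hbo_amplitude,
                 hb_to_hbo_ratio = hb_to_hbo_ratio,
                 lateralization = lateralization,
                 trial_gain_sdlog = trial_gain_sdlog,
                 trial_onset_jitter = trial_onset_jitter),
            class = "hdr_params")
}

#' Physiological noise parameters
#'
#' Each sinusoidal component (cardiac pulsation, respiration, Mayer waves) is
#' added to every channel/chromophore series with an independently seeded
#' phase; Hb series receive the same components scaled by the magnitude of
#' `hb_to_hbo_ratio` so both chromophores share the simulated signal-to-noise
#' ratio. Baseline drift is a seeded Gaussian random walk low-passed below
#' `drift` cutoff and rescaled to the requested amplitude; white measurement
#' noise is i.i.d. Gaussian.
#'
#' Defaults emulate the low single-trial signal-to-noise ratio typical of
#' prefrontal workload recordings, where spontaneous low-frequency
#' oscillations rival or exceed the task-evoked response. The default
#' component frequencies are deliberately incommensurate with the 30 s
#' block-design grid: physiological rhythms are not phase-locked to task
#' onsets, and commensurate frequencies would repeat with identical phase in
#' every trial, turning noise into a fixed per-trial pattern.
#'
#' @param cardiac,respiration,mayer Length-2 numeric vectors
#'   `c(frequency_hz, amplitude_um)`.
#' @param drift Length-2 numeric vector `c(cutoff_hz, amplitude_um)`; the
#'   cutoff must lie below 0.01 Hz so that drift is the detrending filter's
#'   target.
#' @param white_sd Standard deviation (micromolar) of white noise on HbO.
#' @param spontaneous Length-2 numeric vector `c(rate_per_min, amplitude_um)`
#'   of task-unrelated spontaneous hemodynamic events: transient activations
#'   with the same response kernel and HbO/Hb anticorrelation as task-evoked
#'   activity, occurring independently per channel at Poisson times throughout
#'   the block (rest periods included). Being genuine hemodynamics, they pass
#'   every filter of the preprocessing chain -- they are the resting-state
#'   fluctuations that make single-trial workload detection hard.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(cardiac = c(1.17, 0.4), respiration = c(0.31, 0.25),
                         mayer = c(0.093, 1.0), drift = c(0.005, 1.5),
                         white_sd = 0.25, spontaneous = c(4, 1.0)) {
  check_pair <- function(x, name, freq_range = NULL) {
    if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x))) {
      stop(sprintf("`%s` must be c(frequency_hz, amplitude_um)", name),
           call. = FALSE)
    }
    if (x[2] < 0) stop(sprintf("`%s` amplitude must be >= 0", name),
                       call. = FALSE)
    if (x[1] <= 0) stop(sprintf("`%s` frequency must be > 0", name),
                        call. = FALSE)
    x
  }
  cardiac <- check_pair(cardiac, "cardiac")
  respiration <- check_pair(respiration, "respiration")
  mayer <- check_pair(mayer, "mayer")
  drift <- check_pair(drift, "drift")
  if (drift[1] >= 0.01) {
    stop("`drift` cutoff must be < 0.01 Hz (below the detrending cutoff)",
         call. = FALSE)
  }
  stop_if_not_scalar_number(white_sd, "white_sd")
  if (white_sd < 0) stop("`white_sd` must be >= 0", call. = FALSE)
  if (!is.numeric(spontaneous) || length(spontaneous) != 2L ||
      any(spontaneous < 0)) {
    stop("`spontaneous` must be c(rate_per_min, amplitude_um), both >= 0",
         call. = FALSE)
  }
  structure(list(cardiac = cardiac, respiration = respiration, mayer = mayer,
                 drift = drift, white_sd = white_sd,
                 spontaneous = spontaneous),
            class = "noise_params")
}

#' Zero physiological noise
#'
#' Convenience constructor for noise-free simulations.
#' @return A `noise_params` object with all amplitudes zero.
#' @export
noise_none <- function() {
  noise_params(cardiac = c(1.17, 0), respiration = c(0.31, 0),
               mayer = c(0.093, 0), drift = c(0.005, 0), white_sd = 0,
               spontaneous = c(0, 0))
}

#' Motion artifact parameters
#'
#' Spikes are one-sample-rise exponential decays (time constant 0.5 s);
#' baseline shifts are step functions. Event times follow a seeded Poisson
#' process per channel; amplitudes are drawn uniformly in \[0.5, 1.5\] times
#' the nominal amplitude with random sign. With `common_mode = TRUE` (the
#' default) the identical artifact series is added to both the HbO and Hb
#' series of the affected channel -- the structure that correlation-based
#' signal improvement ([cbsi()]) is designed to remove.
#'
#' @param spike_rate,shift_rate Events per minute (>= 0).
#' @param spike_amplitude,shift_amplitude Nominal artifact amplitudes in
#'   micromolar (>= 0).
#' @param common_mode Add the same artifact to HbO and Hb of a channel?
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(spike_rate = 2, spike_amplitude = 5,
                          shift_rate = 0.5, shift_amplitude = 2,
                          common_mode = TRUE) {
  for (nm in c("spike_rate", "spike_amplitude", "shift_rate",
               "shift_amplitude")) {
    v <- get(nm)
    stop_if_not_scalar_number(v, nm)
    if (v < 0) stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
  }
  if (!is.logical(common_mode) || length(common_mode) != 1L) {
    stop("`common_mode` must be TRUE or FALSE", call. = FALSE)
  }
  structure(list(spike_rate = spike_rate, spike_amplitude = spike_amplitude,
                 shift_rate = shift_rate, shift_amplitude = shift_amplitude,
                 common_mode = common_mode),
            class = "motion_params")
}

#' No motion artifacts
#'
#' Default for motion-restricted blocks.
#' @return A `motion_params` object with both event rates zero.
#' @export
motion_none <- function() {
  motion_params(spike_rate = 0, spike_amplitude = 0,
                shift_rate = 0, shift_amplitude = 0)
}

#' Filter settings for the preprocessing chain
#'
#' @param detrend_cut Cutoff (Hz) of the low-pass filter whose output is
#'   subtracted during detrending.
#' @param smooth_cut Cutoff (Hz) of the smoothing low-pass filter.
#' @param sg_degree Savitzky-Golay polynomial order (>= 1).
#' @param cbsi_enabled Apply correlation-based motion correction after
#'   smoothing?
#' @return An object of class `filter_settings`.
#' @seealso [preprocess_pipeline()]
#' @export
filter_settings <- function(detrend_cut = 0.01, smooth_cut = 0.15,
                            sg_degree = 1, cbsi_enabled = TRUE) {
  stop_if_not_scalar_number(detrend_cut, "detrend_cut", positive = TRUE)
  stop_if_not_scalar_number(smooth_cut, "smooth_cut", positive = TRUE)
  if (!is_scalar_count(sg_degree) || sg_degree < 1) {
    stop("`sg_degree` must be an integer >= 1", call. = FALSE)
  }
  if (detrend_cut >= smooth_cut) {
    stop("`detrend_cut` must be below `smooth_cut`", call. = FALSE)
  }
  if (!is.logical(cbsi_enabled) || length(cbsi_enabled) != 1L) {
    stop("`cbsi_enabled` must be TRUE or FALSE", call. = FALSE)
  }
  structure(list(detrend_cut = detrend_cut, smooth_cut = smooth_cut,
                 sg_degree = as.integer(sg_degree),
                 cbsi_enabled = cbsi_enabled),
            class = "filter_settings")
}
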