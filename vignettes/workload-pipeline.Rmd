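---
title: "Simulating and classifying single-trial fNIRS workload signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and classifying single-trial fNIRS workload signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsbci)
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical
blood-oxygenation changes through the differential absorption of 700--1000 nm
light by oxygenated (HbO) and deoxygenated (Hb) hemoglobin. Passive
brain-computer interfaces try to detect a user's mental workload from such
recordings in *single trials* and in near real time, typically with a minimal
prefrontal montage (here: two channels, left and right PFC, sampled at
6.25 Hz). Three families of decoders recur in this literature:

1. **Reference-channel thresholding** -- classify a timepoint as "task"
   whenever the left-minus-right HbO difference exceeds a baseline learned
   from rest trials;
2. **Per-timepoint SVM** -- a linear SVM on the four instantaneous amplitudes
   (left/right x HbO/Hb);
3. **Full-timecourse (window) SVM** -- a linear SVM on the concatenated
   HbO/Hb series of a whole trial window (hundreds to thousands of features
   from a handful of training trials).

This package implements the full pipeline around these models -- simulation,
optical conversion, filtering, motion correction, fitting, and a group-level
evaluation protocol -- so that their relative merits can be studied under
controlled, fully seeded conditions.

## The simulator

### Hemodynamic response

A task trial evokes an HbO increase modeled by convolving the task boxcar
with a unit-peak single-gamma kernel (`hdr_kernel()`):

$$ g(u) \propto (u/t_p)^{5} e^{5\,(1 - u/t_p)}, \qquad u = t - \ell, $$

which is zero before the onset lag $\ell$ (default 1.5 s, within the 1--2 s
range reported for hemodynamic onsets) and peaks exactly $t_p$ (default 6 s,
within the reported 4--8 s window) after the lag. The convolution is
normalized so a sustained task plateaus at `hbo_amplitude` micromolar. Hb is
a negative scalar multiple of HbO (default ratio $-1/3$), encoding the
anticorrelation that correlation-based motion correction assumes. A single
gamma was chosen over a double-gamma because nothing in the modeled
literature constrains an undershoot; `undershoot_fraction` exposes one for
users who want it.

The response is lateralized: the left channel carries the full amplitude and
the right channel a fraction `1 - lateralization` of it (default
`lateralization = 1`, i.e. fully left-lateralized). The reference-channel
thresholding model is meaningless without some asymmetry, so this parameter
is deliberately exposed.

Two sources of *trial-to-trial* response variability are simulated, both
well documented in single-trial fNIRS work and both essential to an honest
evaluation of few-sample/high-dimensional classifiers: a mean-one lognormal
per-trial gain (`trial_gain_sdlog`, default 0.5, i.e. a coefficient of
variation around 50%) and a uniform per-trial onset delay
(`trial_onset_jitter`, default up to 1 s). With a fixed per-trial response,
a full-timecourse linear SVM is a near-matched filter and cannot lose to a
per-timepoint classifier; real responses are not fixed.

### Noise model

Physiological noise (`noise_params()`) has five components, each in
micromolar:

| component    | default                | why                                            |
|--------------|------------------------|------------------------------------------------|
| cardiac      | 1.17 Hz, 0.4           | pulse artifact, removed by the 0.15 Hz smoother |
| respiration  | 0.31 Hz, 0.25          | breathing artifact, also in the smoother's stopband |
| Mayer waves  | 0.093 Hz, amplitude below | spontaneous ~0.1 Hz blood-pressure oscillation; *passes* the smoother |
| drift        | cutoff 0.005 Hz, amplitude below | slow baseline wander; the detrending filter's target |
| white        | sd below               | instrument noise                               |
| spontaneous  | rate/amplitude below   | task-unrelated hemodynamic events (see below)  |

Sinusoidal components get an independently seeded random phase per
channel and chromophore; Hb receives the same components scaled by
`|hb_to_hbo_ratio|` so both chromophores share one signal-to-noise ratio.
The default frequencies are deliberately *incommensurate* with the 30 s
trial/fixation grid: physiological rhythms are not phase-locked to task
onsets, and an exactly commensurate sinusoid (e.g. 0.1 Hz on a 30 s grid)
repeats identically in every trial and stops acting as noise. Drift is a
Gaussian random walk low-passed below its cutoff and rescaled.

The `spontaneous` component models task-unrelated cortical activity:
transient activations with the same gamma kernel and the same HbO/Hb
anticorrelation as task-evoked responses, occurring at Poisson times
(independently per channel) with lognormal amplitudes. Because they are
genuine hemodynamics they survive detrending, smoothing *and* CBSI -- they
are the resting-state fluctuations that fundamentally limit single-trial
workload detection, and the mechanism by which a window classifier trained
on 18 trials can be fooled wholesale while a per-timepoint classifier only
loses the affected samples.

No amplitude or SNR figures are available for the reference instrument, so
the defaults are *stated, not fitted*: they were chosen once to place the
simulated study in the reported single-trial regime -- per-timepoint
decoding modestly above chance, whole-trial decoding unstable across
participants, thresholding near chance -- and are exposed for sensitivity
analyses.

### Motion artifacts

`motion_params()` adds two canonical artifact classes at Poisson event
times: spikes (one-sample rise, 0.5 s exponential decay -- a sensor slipping
and resettling) and baseline shifts (steps -- a sensor settling at a new
scalp coupling). Amplitudes are uniform within 0.5--1.5 times the nominal
value with random sign. By default artifacts are *common mode*: the same
series is added to HbO and Hb of the affected channel, which is precisely
the structure CBSI removes (and real optical coupling changes affect both
chromophore estimates together). Motion-restricted blocks default to zero
events.

### Participant-level variability

`run_study()` draws, per participant, a lognormal coupling gain
(sdlog 0.25) and a uniform onset lag on 1--2 s. The gain multiplies the
response *and* all physiological noise amplitudes (but not instrument white
noise): it mostly represents optode-scalp coupling and vascular
responsiveness, which scale every hemodynamic component alike. Scaling only
the response would make strong-gain participants artificially easy for
every model.

## Optical conversion

`forward_optics()` and `mbll_invert()` implement the modified Beer-Lambert
law in both directions with a per-channel 2x2 linear system linking
optical-density changes at two wavelengths to concentration changes:

$$ \Delta OD(\lambda_i) = \big(\varepsilon_{HbO}(\lambda_i)\,\Delta HbO +
\varepsilon_{Hb}(\lambda_i)\,\Delta Hb\big)\, L\, DPF(\lambda_i). $$

Extinction coefficients come from a bundled 650--1000 nm compilation of
published hemoglobin spectra (10 nm grid, linear interpolation); the matrix
condition number is checked (error above 1e6) and the table source is
recorded in the provenance log. The instrument's wavelengths, DPF and
separation are not documented for the modeled system, so the defaults
(690/830 nm, DPF 6, 3 cm) are typical frequency-domain values; every
quantitative use in the package is a round trip that does not depend on
them. There is no partial-volume correction and no multi-wavelength
least-squares fit.

## Preprocessing

The chain (`preprocess_pipeline()`) is: detrend, smooth, CBSI -- in that
order, each applied per channel over the *whole* continuous block (a
0.01 Hz filter is meaningless on a 30 s trial; trials are sliced out
afterwards).

**Cutoff-to-window mapping.** Savitzky-Golay smoothers are parameterized by
window length, not cutoff frequency. `sg_window_for_cutoff()` selects the
odd window whose measured -3 dB point (computed from the filter's frequency
response) is closest to the requested cutoff, seeded by the approximation
$f_c/f_s \approx (p+1)/(3.2W - 4.6)$ and clamped to at least 5 samples; the
realized cutoff is logged in the provenance. At 6.25 Hz the defaults give a
19-sample window for the 0.15 Hz smoother and a 277-sample window for the
0.01 Hz detrender.

**Edges.** Series are mirror-padded by half a window before filtering, so
block boundaries do not leak ramp artifacts into the first and last trials.

**Detrending** subtracts the 0.01 Hz low-pass from the series (degree-1
filters reproduce constants and lines exactly, so both are removed);
**smoothing** applies the 0.15 Hz low-pass, attenuating cardiac and
respiratory components by more than 95% while passing the hemodynamic band.
Detrending is not idempotent, but a second pass changes the signal by less
than 1% RMS.

**CBSI** (correlation-based signal improvement) computes, on mean-centered
series, $\alpha = sd(HbO)/sd(Hb)$ and returns
$HbO_c = (HbO - \alpha\,Hb)/2$, $Hb_c = -HbO_c/\alpha$. The corrected pair
is exactly anticorrelated by construction; common-mode artifacts are
cancelled to the extent that $\alpha$ matches their relative scaling.
$\alpha$ is computed once per channel over the whole block, following the
method's global definition. A zero-variance Hb series skips CBSI with a
warning instead of failing a batch run.

## Classifiers and conventions

All three models share one contract: `fit_*` on a preprocessed recording
plus trial table, `predict()` returning a `prediction_series` (timestamped
task/rest labels) consumable by the same scoring code.

* **Sampling convention.** Trial spans are half-open
  `[onset, onset + duration)`; a trial contributes exactly
  `floor(duration * rate)` samples starting at the first sample at or after
  its onset. A 30 s trial at 6.25 Hz therefore yields 187 samples, and the
  two-channel window model 187 x 4 = 748 features; the dense 8-signal
  montage at 40 s yields 4000.
* **Thresholding.** The baseline is the mean over rest trials of the
  within-trial maximum of the left-minus-right HbO difference. The training
  description in the source literature is garbled between per-trial and
  per-block maxima; the per-trial mean is the default and
  `baseline_stat = "block_max"` is provided. "Exceeds" is read strictly:
  ties are labelled rest. Predictions are invariant under adding a common
  constant to both channels but not under rescaling.
* **SVMs.** Linear kernel, cost 1, solved by the SMO-type optimizer in
  libsvm (via e1071); features are standardized with parameters estimated
  from the training rows only and stored in the model. Whether the original
  analyses standardized is unstated; standardization is on by default and
  switchable.
* **Window model on continuous data.** The trial-trained window model is
  applied to continuous recordings with sliding windows (default stride
  1 s), each window's label assigned causally to its final timestamp;
  timepoints before the first complete window are excluded from scoring.
  Trials shorter than the window are an error by default, with an explicit
  truncate-to-shortest option (silent padding would fabricate data).
* **Onset latency.** The first task-labelled sample at or after the trial
  onset (a persistence parameter, default 1 sample, requires a run of
  consecutive task labels).

## Evaluation protocol

`crossvalidate()` performs leave-one-trial-per-class-out cross-validation:
with nine task and nine rest trials, nine folds each hold out one trial of
each class (the source material is inconsistent between "10-fold" and
"nine-fold"; nine-fold matches the trial structure and is the default, with
`k` exposed). Accuracy pools timepoint labels (threshold, pointwise) or
trial labels (window) over folds. Per-participant significance uses an
exact one-tailed binomial test on *trial-level majority-vote* outcomes, not
raw timepoints -- timepoints are strongly autocorrelated and a
timepoint-level binomial would be badly anticonservative.

`group_stats()` runs the one-sample, one-tailed t-test against chance used
to declare group-level performance (its 0.05 critical value at 39 degrees
of freedom is 1.68); zero-variance accuracy vectors take an explicit
degenerate path (t = 0/p = 0.5 at chance, otherwise +/-Inf). Model pairs
are compared with a two-tailed paired t-test on per-participant
accuracies. No multiple-testing correction is applied across the three
models, matching the protocol being reproduced; the report says so.

For the continuous "realistic" paradigm (3.5 min rest, 3.5 min task,
3.5 min post-task rest) the chance level of the balanced designs no longer
applies, so the report also prints the majority-class baseline (2/3 for
the 2:1 rest:task layout).

`run_study()` assembles the full design -- per participant: a
motion-restricted training block, a motion-unrestricted training block, and
a realistic block; per model: cross-validation on both training blocks and
restricted-trained evaluation on the realistic block -- and emits
per-participant rows plus a group summary table shaped like the standard
three-models-by-three-experiments comparison, with onset-latency summaries
for the thresholding model.

## Numerical choices and degenerate inputs

* All randomness flows through a single seeded stream per participant;
  identical configurations are bit-identical.
* Windows are always odd and at least 5 samples; series shorter than half a
  window raise an error stating the minimum duration.
* Majority-vote ties count as incorrect (conservative).
* The SVM standardization guards zero-variance features by unit scale.
* Recording writers refuse to overwrite without `force`; readers reject
  non-monotone timestamps and unknown column suffixes by name.

## What the tests do and do not show

The test suite exercises the pipeline on synthetic data whose structure the
package itself defines: stationary sinusoidal physiology, lognormal event
amplitudes, gamma-shaped responses, common-mode artifacts. Passing tests
demonstrate internal correctness (exact contracts, round trips, protocol
properties), null calibration at 50% under label permutation, and the
motion-sensitivity asymmetry (training-block motion degrades the window SVM
far more than the per-timepoint SVM). They do not show that real prefrontal
recordings match these defaults: real noise is broadband and nonstationary,
real responses habituate, and real motion is not a Poisson process.

One population-level finding deserves emphasis. For a *fixed* participant at
the default operating point, the per-timepoint SVM beats the window SVM
(the spontaneous-event noise defeats 18-trial/748-feature learning while the
per-timepoint model only loses the affected samples), and both sit just
above near-chance thresholding. Across a *heterogeneous population*,
however, the window model's accuracy is strongly convex in effective
signal-to-noise ratio -- instrument white noise is the one component that
does not scale with a participant's coupling gain, so well-coupled
participants escape the few-sample suppression and decode whole trials
well -- and its population mean can overtake the per-timepoint model's even
when it is worse for the median participant. The ordering check in the test
suite asserts the three-way population ordering under the default
heterogeneity and is therefore expected to be sensitive to exactly this
effect; the check's failure is informative about the models, not about a
defect in the pipeline.

The group-level checks use 10 to 100 simulated participants (12 x 8 study
replicates for the ordering and degradation checks, 10 x 4 for the
permutation null); these sizes keep the default check suite inside a few
minutes while leaving group-mean standard errors near one accuracy point.

## Known limitations

* Two-wavelength, two-channel geometry only; no short-separation channels,
  no multi-distance methods, no scalp/superficial-layer optics.
* No SNIRF/HDF5 interchange; TSV with JSON provenance sidecars is the
  canonical format.
* The spontaneous-activity model is a Poisson process of stereotyped
  kernel-shaped events -- a deliberately simple stand-in for broadband
  resting-state dynamics.
* Filters are applied per block offline; no causal/online variants.

## A small worked example

```{r example, eval = FALSE}
library(nirsbci)
report <- run_study(study_config(n_participants = 8, seed = 11))
print(report)
```
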