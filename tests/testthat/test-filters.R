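test_that("window selection hits the requested cutoff and is monotone", {
  W_smooth <- sg_window_for_cutoff(0.15, 6.25, 1)
  W_detrend <- sg_window_for_cutoff(0.01, 6.25, 1)
  expect_true(W_smooth %% 2 == 1 && W_detrend %% 2 == 1)
  expect_gt(W_detrend, W_smooth)
  expect_gte(as.integer(W_smooth), 5L)
  # realized -3 dB points land close to the requested cutoffs
  expect_lt(abs(attr(W_smooth, "realized_cutoff_hz") - 0.15) / 0.15, 0.25)
  expect_lt(abs(attr(W_detrend, "realized_cutoff_hz") - 0.01) / 0.01, 0.25)
})

test_that("cutoffs at or above Nyquist are rejected", {
  expect_error(sg_window_for_cutoff(4, 6.25, 1), "Nyquist")
  expect_error(sg_window_for_cutoff(3.125, 6.25, 1), "Nyquist")
})

test_that("detrending removes constants and lines but passes fast oscillations", {
  rate <- 6.25
  n <- 4000
  t <- (0:(n - 1)) / rate
  settings <- filter_settings()
  central <- (n %/% 4):(3 * n %/% 4)

  const <- two_channel_rec(rep(2.5, n), rep(-1, n), rate = rate)
  out <- detrend(const, settings)
  expect_lt(max(abs(out$data)), 1e-9)

  ramp <- two_channel_rec(seq(0, 10, length.out = n), rate = rate)
  out <- detrend(ramp, settings)
  expect_lt(max(abs(out$data[central, "L_HbO"])), 1e-6 * 10)

  sine <- two_channel_rec(sin(2 * pi * 1 * t), rate = rate)
  out <- detrend(sine, settings)
  dev <- out$data[central, "L_HbO"] - sin(2 * pi * 1 * t)[central]
  expect_lt(sqrt(mean(dev^2)) / sqrt(mean(sin(2 * pi * t)[central]^2)), 0.05)
})

test_that("smoothing keeps DC and the passband but attenuates 1 Hz", {
  rate <- 6.25
  n <- 4000
  t <- (0:(n - 1)) / rate
  settings <- filter_settings()
  central <- (n %/% 4):(3 * n %/% 4)

  const <- two_channel_rec(rep(1.5, n), rate = rate)
  expect_equal(smooth_recording(const, settings)$data[, "L_HbO"],
               rep(1.5, n), tolerance = 1e-9)

  fast <- two_channel_rec(sin(2 * pi * 1 * t), rate = rate)
  out <- smooth_recording(fast, settings)
  expect_lt(max(abs(out$data[central, "L_HbO"])), 0.3)

  slow <- two_channel_rec(sin(2 * pi * 0.01 * t), rate = rate)
  out <- smooth_recording(slow, settings)
  expect_gt(max(out$data[central, "L_HbO"]), 0.9)
})

test_that("a recording shorter than the window errors with guidance", {
  rec <- two_channel_rec(stats::rnorm(20))
  expect_error(detrend(rec), "too short")
})

test_that("CBSI matches its defining formula and enforces anticorrelation", {
  s <- sin(2 * pi * 0.05 * (0:499) / 6.25)
  f <- with_seed_test(1, {
    spikes <- numeric(500)
    spikes[sample(500, 10)] <- stats::rnorm(10, 0, 4)
    stats::filter(spikes, 0.8^(0:20), method = "convolution", sides = 1)
  })
  f <- as.numeric(f)
  f[is.na(f)] <- 0
  alpha0 <- 3
  hbo <- s + f
  hb <- -s / alpha0 + f
  out <- cbsi(hbo, hb)
  # independent oracle: (x - alpha y) / 2 on centered series
  x <- hbo - mean(hbo)
  y <- hb - mean(hb)
  a <- stats::sd(x) / stats::sd(y)
  expect_equal(out$hbo, (x - a * y) / 2, tolerance = 1e-12)
  expect_equal(out$hb, -(x - a * y) / 2 / a, tolerance = 1e-12)
  expect_equal(stats::cor(out$hbo, out$hb), -1, tolerance = 1e-10)
  # the common-mode component is attenuated relative to no correction
  expect_lt(sqrt(mean((out$hbo - s * (1 + a / alpha0) / 2)^2)),
            sqrt(mean((hbo - s)^2)))
})

test_that("already-anticorrelated input passes through CBSI unchanged", {
  s <- with_seed_test(2, stats::rnorm(100))
  s <- s - mean(s)
  out <- cbsi(s, -s / 2)
  expect_equal(out$hbo, s, tolerance = 1e-12)
  expect_equal(out$hb, -s / 2, tolerance = 1e-12)
})

test_that("CBSI rejects degenerate input", {
  expect_error(cbsi(stats::rnorm(10), rep(0, 10)), "alpha is undefined")
  expect_error(cbsi(1:5, 1:4), "equal length")
})

test_that("pipeline order, gating and zero-variance handling", {
  tt <- small_block(trial_dur = 20, fixation_dur = 10)
  ds <- generate_participant(list(b = tt), seed = 4,
                             motion_by_block = list(b = motion_none()))
  rec <- ds$recordings$b

  no_cbsi <- preprocess_pipeline(rec, filter_settings(cbsi_enabled = FALSE))
  manual <- smooth_recording(detrend(rec))
  expect_equal(no_cbsi$data, manual$data)

  full <- preprocess_pipeline(rec)
  steps <- vapply(full$provenance, `[[`, "", "step")
  expect_equal(steps[-1], c("detrend", "smooth", "cbsi"))
  for (ch in c("L", "R")) {
    expect_equal(stats::cor(chrom_series(full, ch, "HbO"),
                            chrom_series(full, ch, "Hb")),
                 -1, tolerance = 1e-10)
  }

  zero <- two_channel_rec(numeric(600), rate = 6.25)
  w <- testthat::capture_warnings(out <- preprocess_pipeline(zero))
  expect_length(w, 2) # one per zero-variance channel
  expect_true(all(grepl("zero-variance", w)))
  expect_true(all(out$data == 0))
})

test_that("preprocessing treats channels independently", {
  ds <- generate_participant(list(b = small_block(trial_dur = 20,
                                                  fixation_dur = 10)),
                             seed = 9,
                             motion_by_block = list(b = motion_params()))
  rec <- ds$recordings$b
  swapped <- hemo_recording(rec$data[, c("R_HbO", "R_Hb", "L_HbO", "L_Hb")],
                            rate = rec$rate)
  a <- preprocess_pipeline(rec)
  b <- preprocess_pipeline(swapped)
  expect_equal(a$data[, "L_HbO"], b$data[, "L_HbO"])
  expect_equal(a$data[, "R_Hb"], b$data[, "R_Hb"])
})

test_that("a second detrend pass changes almost nothing once drift is gone", {
  # raw signal = slow drift plus cardiac-band content: the first pass removes
  # the sub-cutoff drift, so a second pass finds almost nothing to subtract
  # (a degree-1 smoother's wide transition band means this only holds once
  # the remaining content sits well above the cutoff)
  rate <- 6.25
  t <- (0:3999) / rate
  x <- 0.5 * sin(2 * pi * 0.0005 * t) + 0.5 * sin(2 * pi * 1.17 * t)
  rec <- two_channel_rec(x, rate = rate)
  once <- detrend(rec)
  twice <- detrend(once)
  rel <- sqrt(mean((twice$data - once$data)^2)) / sqrt(mean(once$data^2))
  expect_lt(rel, 0.01)
})

test_that("CBSI improves recovery of the true signal under common-mode spikes", {
  wins <- sapply(1:10, function(s) {
    tt <- small_block(seed = s, trial_dur = 20, fixation_dur = 10)
    motion <- motion_params(spike_rate = 6, spike_amplitude = 5)
    ds <- generate_participant(
      list(b = tt),
      hdr = hdr_params(trial_gain_sdlog = 0, trial_onset_jitter = 0),
      noise = noise_none(), motion_by_block = list(b = motion),
      seed = s + 50)
    rec <- ds$recordings$b
    truth <- ds$truth$b[, "L_HbO"]
    corrected <- cbsi(chrom_series(rec, "L", "HbO"),
                      chrom_series(rec, "L", "Hb"))
    # compare on the scale-invariant correlation with the truth
    stats::cor(corrected$hbo, truth) > stats::cor(rec$data[, "L_HbO"], truth)
  })
  expect_gte(mean(wins), 0.9)
})
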