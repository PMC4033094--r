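test_that("diff_series subtracts the reference channel and cancels common offsets", {
  rec <- two_channel_rec(c(1, 2), c(0.5, 0.5))
  expect_equal(diff_series(rec), c(0.5, 1.5))
  same <- two_channel_rec(c(1, 2), c(1, 2))
  expect_equal(diff_series(same), c(0, 0))
  shifted <- two_channel_rec(c(1, 2) + 7, c(0.5, 0.5) + 7)
  expect_equal(diff_series(shifted), c(0.5, 1.5))
  expect_error(diff_series(rec, "L", "L"), "must differ")
  expect_error(diff_series(rec, "L", "Z"), "no series")
})

test_that("threshold baseline is the mean of within-rest-trial maxima", {
  rate <- 6.25
  n <- 500
  l <- numeric(n)
  t <- (0:(n - 1)) / rate
  # two rest trials with known diff maxima 0.3 and 0.5
  l[t >= 0 & t < 20] <- 0.1
  l[abs(t - 10) < 0.1] <- 0.3
  l[t >= 30 & t < 50] <- 0.2
  l[abs(t - 40) < 0.1] <- 0.5
  rec <- two_channel_rec(l, rate = rate)
  tt <- trial_table(c(0, 30), c(20, 20), c("rest", "rest"), "b")
  m <- fit_threshold(rec, tt)
  expect_equal(m$baseline, 0.4)
  expect_equal(fit_threshold(rec, tt, baseline_stat = "block_max")$baseline,
               0.5)
  # constant diff: baseline equals the constant
  const <- two_channel_rec(rep(0.2, n), rate = rate)
  expect_equal(fit_threshold(const, tt)$baseline, 0.2)
  # all-zero diff
  expect_equal(fit_threshold(two_channel_rec(numeric(n), rate = rate),
                             tt)$baseline, 0)
  expect_error(fit_threshold(rec, trial_table(0, 10, "task", "b")),
               "no rest trials")
})

test_that("threshold prediction is strict and offset-invariant", {
  m <- structure(list(baseline = 0.4, target = "L", reference = "R",
                      baseline_stat = "mean_of_trial_max"),
                 class = "threshold_model")
  rec <- two_channel_rec(c(0.2, 0.5), c(0, 0))
  expect_equal(as.character(predict(m, rec)$label), c("rest", "task"))
  # ties go to rest
  tie <- two_channel_rec(c(0.4, 0.4))
  expect_equal(as.character(predict(m, tie)$label), c("rest", "rest"))
  # adding a common constant to both channels changes nothing
  shifted <- two_channel_rec(c(0.2, 0.5) + 3, c(3, 3))
  expect_equal(predict(m, shifted)$label, predict(m, rec)$label)
  # negative baseline labels any positive difference as task
  m$baseline <- -5
  expect_equal(as.character(predict(m, rec)$label), c("task", "task"))
})

test_that("onset latency reflects the first task-labelled sample", {
  rate <- 6.25
  time <- (0:199) / rate
  labels <- rep("rest", 200)
  labels[21] <- "task" # sample index 20 (0-based) => 3.2 s after onset 0
  pred <- structure(data.frame(time = time,
                               label = factor(labels,
                                              levels = c("rest", "task"))),
                    class = c("prediction_series", "data.frame"))
  expect_equal(detect_onset(pred, 0, 30), 3.2)
  expect_true(is.na(detect_onset(pred, 10, 10)))
  labels2 <- labels
  labels2[1] <- "task"
  pred2 <- structure(data.frame(time = time,
                                label = factor(labels2,
                                               levels = c("rest", "task"))),
                     class = c("prediction_series", "data.frame"))
  expect_equal(detect_onset(pred2, 0, 30), 0)
  # persistence requires a run of consecutive task labels
  expect_true(is.na(detect_onset(pred2, 0, 30, persistence = 2)))
  expect_error(detect_onset(pred, 100, 30), "outside")
})

test_that("pointwise featurization uses the floor convention and fixed order", {
  tt <- trial_table(c(0, 60), c(30, 30), c("task", "rest"), "b")
  ds <- clean_participant(trial_table(c(0, 60), c(30, 30), c("task", "rest"),
                                      "b"))
  rec <- ds$recordings$b
  s <- featurize_pointwise(rec, tt)
  expect_equal(nrow(s$design), 2 * 187) # floor(30 * 6.25) per trial
  expect_equal(colnames(s$design), c("L_HbO", "L_Hb", "R_HbO", "R_Hb"))
  expect_equal(as.character(unique(s$labels)), c("task", "rest"))
  # row values equal the recording at the matching timestamp
  i <- 42
  j <- which(abs(rec$time - s$meta$time[i]) < 1e-9)
  expect_equal(unname(s$design[i, ]), unname(rec$data[j, ]))
  # an empty trial table is a valid, empty design
  empty <- s0 <- featurize_pointwise(rec, tt[0, ])
  expect_equal(nrow(empty$design), 0)
})

test_that("window featurization has the documented dimensionality", {
  ds <- clean_participant(trial_table(c(0, 60), c(30, 30), c("task", "rest"),
                                      "b"))
  rec <- ds$recordings$b
  s <- featurize_window(rec, ds$trials$b, window_duration = 30)
  expect_equal(ncol(s$design), 748) # 187 samples x 2 chromophores x 2 channels
  expect_equal(nrow(s$design), 2)
  # channel-major, chromophore, time ordering
  idx <- trial_sample_index_for_test(rec, 0, 30)
  expect_equal(unname(s$design[1, 1:187]), unname(rec$data[idx, "L_HbO"]))
  expect_equal(unname(s$design[1, 188:374]), unname(rec$data[idx, "L_Hb"]))

  # the classic dense-montage geometry: 8 optode signals x 2 chromophores at
  # 40 s and 6.25 Hz gives 4000 features
  x <- matrix(stats::rnorm(300 * 16), 300, 16)
  colnames(x) <- paste0(rep(paste0("C", 1:8), each = 2), c("_HbO", "_Hb"))
  rec8 <- hemo_recording(x, rate = 6.25)
  tt40 <- trial_table(0, 40, "task", "b")
  expect_equal(ncol(featurize_window(rec8, tt40, 40)$design), 4000)

  expect_error(featurize_window(rec, ds$trials$b, 0), "window_duration")
  expect_error(featurize_window(rec, ds$trials$b, 60), "shorter than")
  trunc <- featurize_window(rec, ds$trials$b, 60, short_trials = "truncate")
  expect_equal(attr(trunc, "window_duration"), 30)
})

test_that("SVM fitting handles separable, degenerate and duplicated input", {
  xs <- structure(list(
    design = rbind(c(0, 0), c(1, 1)),
    labels = factor(c("rest", "task"), levels = c("rest", "task")),
    meta = data.frame(trial = 1:2, time = c(0, 1))),
    class = "labeled_samples")
  colnames(xs$design) <- c("a", "b")
  m <- fit_svm(xs, "pointwise")
  rec_like <- xs$design
  xs_std <- sweep(sweep(rec_like, 2, m$center, "-"), 2, m$scale, "/")
  colnames(xs_std) <- colnames(m$fit$SV)
  expect_equal(as.character(predict(m$fit, xs_std)), c("rest", "task"))

  one_class <- xs
  one_class$labels <- factor(c("task", "task"), levels = c("rest", "task"))
  expect_error(fit_svm(one_class, "pointwise"), "both classes")

  # duplicating every row (both classes equally) leaves the decision
  # function essentially unchanged
  big <- with_seed_test(3, {
    d <- matrix(stats::rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
    lab <- factor(rep(c("rest", "task"), 20), levels = c("rest", "task"))
    d[lab == "task", 1] <- d[lab == "task", 1] + 2
    structure(list(design = d, labels = lab,
                   meta = data.frame(trial = 1:40, time = 1:40)),
              class = "labeled_samples")
  })
  dup <- big
  dup$design <- rbind(big$design, big$design)
  dup$labels <- factor(rep(as.character(big$labels), 2),
                       levels = c("rest", "task"))
  dup$meta <- rbind(big$meta, big$meta)
  m1 <- fit_svm(big, "pointwise")
  m2 <- fit_svm(dup, "pointwise")
  grid <- matrix(stats::rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  g1 <- predict(m1$fit, sweep(sweep(grid, 2, m1$center), 2, m1$scale, "/"))
  g2 <- predict(m2$fit, sweep(sweep(grid, 2, m2$center), 2, m2$scale, "/"))
  expect_gte(mean(g1 == g2), 0.95)
})

test_that("pointwise SVM recovers a separable noise-free simulation", {
  # long plateau-dominated trials: only the hemodynamic rise (a few seconds
  # of each 90 s trial) is intrinsically ambiguous at the timepoint level
  tt <- small_block(seed = 2, n_task = 2, n_rest = 2, trial_dur = 90,
                    fixation_dur = 10)
  ds <- clean_participant(tt, hbo_amplitude = 1)
  rec <- ds$recordings$b
  s <- featurize_pointwise(rec, tt)
  m <- fit_svm(s, "pointwise")
  pred <- predict(m, rec, trials = tt)
  sc <- score_predictions(pred, tt)
  expect_gte(sc$accuracy, 0.95)
  # the window model nails whole trials
  mw <- fit_svm(featurize_window(rec, tt, 90), "window")
  predw <- predict(mw, rec, trials = tt)
  expect_equal(score_predictions(predw, tt)$accuracy, 1)
})

test_that("geometry mismatches and empty inputs are explicit", {
  tt <- small_block(seed = 2, n_task = 3, n_rest = 3, trial_dur = 20,
                    fixation_dur = 10)
  ds <- clean_participant(tt)
  m <- fit_svm(featurize_pointwise(ds$recordings$b, tt), "pointwise")
  x3 <- matrix(stats::rnorm(60), 10, 6)
  colnames(x3) <- paste0(rep(c("A", "B", "C"), each = 2), c("_HbO", "_Hb"))
  rec3 <- hemo_recording(x3, rate = 6.25)
  expect_error(predict(m, rec3), "dimension mismatch")
  empty_pred <- predict(m, ds$recordings$b, trials = tt[0, ])
  expect_equal(nrow(empty_pred), 0)
})

test_that("all three models emit scoreable prediction series", {
  tt <- small_block(seed = 5, n_task = 2, n_rest = 2, trial_dur = 20,
                    fixation_dur = 10)
  ds <- generate_participant(list(b = tt), seed = 6,
                             motion_by_block = list(b = motion_none()))
  rec <- preprocess_pipeline(ds$recordings$b)
  models <- list(
    threshold = fit_threshold(rec, tt),
    pointwise = fit_svm(featurize_pointwise(rec, tt), "pointwise"),
    window = fit_svm(featurize_window(rec, tt, 20), "window"))
  for (nm in names(models)) {
    pred <- if (nm == "threshold") predict(models[[nm]], rec) else
      predict(models[[nm]], rec, trials = tt)
    expect_s3_class(pred, "prediction_series")
    sc <- score_predictions(pred, tt)
    expect_true(sc$n_total > 0)
    expect_true(sc$accuracy >= 0 && sc$accuracy <= 1)
  }
})
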