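test_that("oracle predictions score perfectly and scoring respects spans", {
  tt <- trial_table(c(0, 40), c(30, 30), c("task", "rest"), "b")
  time <- (0:499) / 6.25
  truth <- rep("rest", 500)
  truth[time >= 0 & time < 30] <- "task"
  pred <- structure(data.frame(time = time,
                               label = factor(truth,
                                              levels = c("rest", "task"))),
                    class = c("prediction_series", "data.frame"))
  sc <- score_predictions(pred, tt)
  expect_equal(sc$accuracy, 1)
  expect_true(all(sc$by_trial$majority_correct))
  # flipping every label gives zero
  flipped <- pred
  flipped$label <- factor(ifelse(truth == "task", "rest", "task"),
                          levels = c("rest", "task"))
  expect_equal(score_predictions(flipped, tt)$accuracy, 0)
})

test_that("nine-fold cross-validation holds out each trial exactly once", {
  tt <- generate_paradigm("training_block", seed = 3, block = "b")
  ds <- generate_participant(list(b = tt), seed = 4,
                             motion_by_block = list(b = motion_none()))
  rec <- preprocess_pipeline(ds$recordings$b)
  cv <- crossvalidate(rec, tt, model = "threshold", k = 9)
  expect_equal(sort(unique(cv$fold)), 1:9)
  expect_true(all(table(cv$fold) == 2))
  expect_equal(cv$n_trials, 18)
  expect_equal(length(cv$latencies), 9) # one per task trial
  expect_true(cv$accuracy >= 0 && cv$accuracy <= 1)
})

test_that("incompatible fold counts propose valid alternatives", {
  tt <- small_block(n_task = 4, n_rest = 4, trial_dur = 10)
  ds <- clean_participant(tt)
  expect_error(crossvalidate(ds$recordings$b, tt, "threshold", k = 3),
               "valid k: 2, 4")
})

test_that("held-out trials cannot influence fitting", {
  tt <- generate_paradigm("training_block", n_task = 3, n_rest = 3,
                          trial_dur = 10, fixation_dur = 10, seed = 5,
                          block = "b")
  ds <- generate_participant(list(b = tt), seed = 6,
                             motion_by_block = list(b = motion_none()))
  rec <- preprocess_pipeline(ds$recordings$b)
  trials <- tt[tt$condition != "fixation", ]
  train <- trials[-c(1, nrow(trials)), ]
  held <- trials[c(1, nrow(trials)), ]
  # poison the held-out spans with absurd values
  poisoned <- rec
  for (i in seq_len(nrow(held))) {
    idx <- trial_sample_index_for_test(rec, held$onset_s[i],
                                       held$duration_s[i])
    poisoned$data[idx, ] <- 1e6
  }
  expect_equal(fit_threshold(rec, train)$baseline,
               fit_threshold(poisoned, train)$baseline)
  s1 <- featurize_pointwise(rec, train)
  s2 <- featurize_pointwise(poisoned, train)
  expect_identical(s1$design, s2$design)
})

test_that("group statistics against chance handle typical and degenerate input", {
  null_case <- group_stats(rep(0.5, 10))
  expect_equal(null_case$t, 0)
  expect_equal(null_case$p, 0.5)
  expect_false(null_case$significant)

  gs <- group_stats(c(0.6, 0.7, 0.8, 0.5, 0.65))
  expect_equal(gs$df, 4)
  manual_t <- (mean(c(0.6, 0.7, 0.8, 0.5, 0.65)) - 0.5) /
    (stats::sd(c(0.6, 0.7, 0.8, 0.5, 0.65)) / sqrt(5))
  expect_equal(gs$t, manual_t)

  const_above <- group_stats(rep(0.6, 4))
  expect_equal(const_above$t, Inf)
  expect_equal(const_above$p, 0)
  expect_error(group_stats(0.6), "two participants")
})

test_that("per-participant significance uses the exact binomial tail", {
  # 9/9 at chance 0.5: p = 0.5^9
  r <- per_participant_significance(9, 9)
  expect_equal(r$p, 0.5^9)
  expect_true(r$significant)
  # 5/9: tail sum C(9,5..9)/2^9 = 256/512 = 0.5
  r <- per_participant_significance(5, 9)
  expect_equal(r$p, 0.5)
  expect_false(r$significant)
  expect_false(per_participant_significance(0, 9)$significant)
  expect_error(per_participant_significance(10, 9), "exceed")
})

test_that("paired model comparison handles identical and constant-shift input", {
  idn <- compare_models(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(idn$t, 0)
  expect_equal(idn$p, 1)
  shift <- compare_models(c(0.6, 0.7, 0.8), c(0.5, 0.6, 0.7))
  expect_equal(shift$t, Inf)
  expect_equal(shift$p, 0)
  a <- c(0.62, 0.55, 0.71, 0.58)
  b <- c(0.51, 0.50, 0.66, 0.52)
  manual <- stats::t.test(a - b)
  got <- compare_models(a, b)
  expect_equal(got$t, unname(manual$statistic))
  expect_equal(got$p, manual$p.value)
  expect_error(compare_models(1:3 / 10, 1:4 / 10), "pair")
})

test_that("paired comparison gains power with sample size at fixed effect", {
  pvals <- vapply(c(6, 12, 24), function(n) {
    # deterministic sample with fixed effect and spread
    d <- 0.05 + 0.08 * stats::qnorm(stats::ppoints(n))
    compare_models(0.5 + d, rep(0.5, n))$p
  }, numeric(1))
  expect_true(all(diff(pvals) < 0))
})

test_that("realistic evaluation scores blocks, reports latency and baseline", {
  tt <- generate_paradigm("realistic", block = "b")
  names_tt <- trial_table(tt$onset_s, tt$duration_s, tt$condition, "b")
  ds <- clean_participant(names_tt)
  rec <- ds$recordings$b
  # an all-rest predictor: threshold far above any observed difference
  all_rest <- structure(list(baseline = 1e9, target = "L", reference = "R",
                             baseline_stat = "mean_of_trial_max"),
                        class = "threshold_model")
  out <- evaluate_realistic(rec, names_tt, list(threshold = all_rest))
  expect_equal(out$accuracy, 2 / 3, tolerance = 1e-3)
  expect_equal(out$majority_baseline, 2 / 3, tolerance = 1e-3)
  expect_true(is.na(out$latency_s))

  # a sub-peak threshold detects the task onset within the rise time
  m <- structure(list(baseline = 0.05, target = "L", reference = "R",
                      baseline_stat = "mean_of_trial_max"),
                 class = "threshold_model")
  out2 <- evaluate_realistic(rec, names_tt, list(threshold = m))
  expect_gte(out2$latency_s, 1.5)
  expect_lte(out2$latency_s, 7.5)
})

test_that("latency summaries aggregate and count missing detections", {
  s <- latency_stats(c(3, 5))
  expect_equal(s$mean, 4)
  expect_equal(s$min, 3)
  expect_equal(s$max, 5)
  expect_equal(s$n_none, 0)
  s2 <- latency_stats(c(NA, 4, 6))
  expect_equal(s2$n_none, 1)
  expect_equal(s2$n, 2)
  expect_error(latency_stats(c(NA_real_, NA_real_)), "no detections")
})

test_that("a small study runs end to end, deterministically", {
  cfg <- study_config(n_participants = 2, seed = 21, n_task = 3, n_rest = 3,
                      trial_dur = 10, fixation_dur = 10, k = 3,
                      window_duration = 10,
                      noise = noise_params(mayer = c(0.093, 0.2),
                                           drift = c(0.005, 0.3),
                                           spontaneous = c(1, 0.2)))
  rep1 <- run_study(cfg)
  expect_equal(nrow(rep1$summary), 9) # 3 models x 3 experiments
  expect_setequal(unique(rep1$per_participant$experiment),
                  c("restricted_cv", "unrestricted_cv", "realistic"))
  expect_setequal(unique(rep1$per_participant$model),
                  c("threshold", "pointwise", "window"))
  expect_true(all(rep1$per_participant$accuracy >= 0 &
                    rep1$per_participant$accuracy <= 1))
  rep2 <- run_study(cfg)
  expect_identical(rep1$per_participant, rep2$per_participant)
  expect_output(print(rep1), "study_report")
})

test_that("experiment subsetting runs only what is requested", {
  cfg <- study_config(n_participants = 2, seed = 8, n_task = 2, n_rest = 2,
                      trial_dur = 10, fixation_dur = 10, k = 2,
                      window_duration = 10,
                      experiments = "restricted_cv")
  rep <- run_study(cfg)
  expect_equal(unique(rep$per_participant$experiment), "restricted_cv")
})
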