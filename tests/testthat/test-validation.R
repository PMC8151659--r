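test_that("event matching pairs closest events within the window", {
  m <- match_events(c(1.000, 2.105), c(1.010, 2.090, 3.000), 0.0333)
  expect_equal(m$TP, 2L)
  expect_equal(m$FN, 1L)
  expect_equal(m$FP, 0L)
  expect_equal(m$matches$offset_s, c(-0.010, 0.015), tolerance = 1e-12)
  expect_equal(sensitivity(m), 100 * 2 / 3, tolerance = 1e-9)

  ident <- match_events(c(1, 2, 3), c(1, 2, 3), 0.0333)
  expect_equal(ident$matches$offset_s, c(0, 0, 0))
  expect_equal(sensitivity(ident), 100)

  none <- match_events(numeric(0), c(1, 2), 0.0333)
  expect_equal(none$TP, 0L)
  expect_equal(none$FN, 2L)
  expect_error(sensitivity(match_events(numeric(0), numeric(0), 0.1)), "undefined")
  expect_error(match_events(1, 1, 0), "positive")
})

test_that("greedy matching equals exhaustive optimal assignment on gait-like instances", {
  set.seed(41)
  tol <- 1 / 30
  for (i in 1:200) {
    inst <- random_match_instance(tol)
    g <- match_events(inst$detected, inst$reference, tol)
    bf <- brute_force_match(inst$detected, inst$reference, tol)
    expect_equal(g$TP, bf$n)
    expect_equal(sum(abs(g$matches$offset_s)), bf$cost, tolerance = 1e-9)
  }
})

test_that("sensitivity is monotone non-decreasing in the tolerance", {
  set.seed(42)
  detected <- sort(runif(20, 0, 20))
  reference <- sort(runif(15, 0, 20))
  tols <- c(0.01, 0.05, 0.1, 0.5, 1, 2)
  sens <- vapply(tols, function(tl) sensitivity(match_events(detected, reference, tl)),
                 numeric(1))
  expect_true(all(diff(sens) >= -1e-12))
})

test_that("MAD outlier mask matches hand computation and degenerate branches", {
  # median 3, MAD 1, scaled 1.4826: only 100 exceeds 3.5 * 1.4826
  expect_equal(mad_outlier_mask(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(mad_outlier_mask(rep(5, 6)), rep(FALSE, 6))
  # MAD == 0 branch: anything off the median is flagged
  expect_equal(mad_outlier_mask(c(0, 0, 0, 0, 1)), c(rep(FALSE, 4), TRUE))
  expect_error(mad_outlier_mask(c(1, 2)), "at least 3")
})

test_that("MAD mask is scale- and shift-equivariant", {
  set.seed(43)
  for (i in 1:20) {
    x <- c(rnorm(20), rnorm(2, 10))
    a <- runif(1, 0.1, 50) * sample(c(-1, 1), 1)
    b <- runif(1, -100, 100)
    expect_equal(mad_outlier_mask(a * x + b), mad_outlier_mask(x))
  }
})

test_that("offset statistics match direct arithmetic", {
  s <- offset_statistics(c(0.010, -0.010))
  expect_equal(s$mean, 0)
  expect_equal(s$abs_mean, 0.010)
  expect_equal(s$rmse, 0.010)

  s <- offset_statistics(c(5, 5, 5))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)
  expect_equal(s$rmse, 5)

  expect_equal(offset_statistics(c(3, -4))$rmse, sqrt((9 + 16) / 2))
  expect_error(offset_statistics(c(1, 2), mask = c(TRUE, TRUE)), "no unmasked")
})

test_that("RMSE decomposes into mean and variance (population identity)", {
  set.seed(44)
  for (i in 1:25) {
    x <- rnorm(sample(3:50, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 3))
    s <- offset_statistics(x)
    n <- s$n
    expect_equal(s$rmse^2, s$mean^2 + s$sd^2 * (n - 1) / n, tolerance = 1e-9)
  }
})

test_that("limits of agreement are mean +/- 1.96 SD", {
  x <- c(-1, 1)   # mean 0, sd sqrt(2)
  expect_equal(limits_of_agreement(x),
               c(lo = -1.96 * sqrt(2), hi = 1.96 * sqrt(2)))
  expect_equal(limits_of_agreement(rep(2.5, 5)), c(lo = 2.5, hi = 2.5))
  set.seed(45)
  z <- rnorm(500)
  z <- (z - mean(z)) / stats::sd(z) * 0.5 + 2    # mean 2, sd 0.5
  expect_equal(limits_of_agreement(z), c(lo = 1.02, hi = 2.98), tolerance = 1e-9)
  expect_error(limits_of_agreement(1), "at least 2")
})

test_that("feature agreement reports zero error on identical tables, NA r on constants", {
  trial <- noiseless_trial(n_strides = 6)
  feats <- trial$truth_features
  pairs <- pair_strides(feats, feats)
  expect_equal(nrow(pairs), nrow(feats))
  fa <- feature_agreement(feats, feats, pairs)
  expect_equal(fa$rmse, rep(0, 5))
  expect_equal(fa$mean_offset, rep(0, 5))
  # truth features are constant across strides: correlation undefined
  expect_true(all(is.na(fa$pearson_r)))
})

test_that("a constant +1 cm stride-length bias is reported exactly", {
  trial <- noiseless_trial(n_strides = 6)
  ref <- trial$truth_features
  vr <- ref
  vr$SL_m <- vr$SL_m + 0.01
  fa <- feature_agreement(vr, ref, pair_strides(vr, ref))
  sl <- fa[fa$feature == "SL", ]
  expect_equal(sl$mean_offset, 0.01, tolerance = 1e-12)
  expect_equal(sl$sd_offset, 0)
  expect_equal(sl$rmse, 0.01, tolerance = 1e-12)
})

test_that("agreement RMSE recovers the scale of injected noise", {
  # perturb a reference table with known Gaussian noise and check the
  # estimated RMSE against the injected scale (chi-squared concentration:
  # ~5% relative error at n = 200)
  set.seed(46)
  trial <- simulate_trial(synthetic_gait_spec(n_strides = 201, noise_sd_pos = 0,
                                              seed = 8))
  ref <- trial$truth_features
  vr <- ref
  sd_sl <- 0.004
  sd_st <- 0.008
  vr$SL_m <- vr$SL_m + rnorm(nrow(vr), 0, sd_sl)
  vr$ST_s <- vr$ST_s + rnorm(nrow(vr), 0, sd_st)
  fa <- feature_agreement(vr, ref, pair_strides(vr, ref))
  expect_equal(fa$rmse[fa$feature == "SL"], sd_sl, tolerance = 0.10)
  expect_equal(fa$rmse[fa$feature == "ST"], sd_st, tolerance = 0.10)
  expect_error(feature_agreement(vr, ref, data.frame(vr_row = 1, ref_row = 1)),
               "at least 2")
})

test_that("validation reports apply the known clock offset before matching", {
  spec <- synthetic_gait_spec(n_strides = 10, noise_sd_pos = 0,
                              clock_offset_s = 0.25, seed = 5)
  trial <- simulate_trial(spec)
  res <- run_trial_pipeline(trial)
  cfg0 <- run_config(sync_offset_s = 0)
  cfg <- run_config(sync_offset_s = 0.25)
  # without compensation nothing matches; with it everything does
  rep0 <- validate_pipeline(res, trial$reference, config = cfg0)
  rep <- validate_pipeline(res, trial$reference, config = cfg)
  expect_equal(rep0$events$HS$sensitivity_pct, 0)
  expect_equal(rep$events$HS$sensitivity_pct, 100)
  expect_equal(rep$events$TO$sensitivity_pct, 100)
  # offsets vs the 120 Hz reference grid stay within half a reference sample
  expect_lte(abs(rep$events$HS$mean_offset_ms) +
               2 * rep$events$HS$sd_offset_ms, 1000 / 90)
})
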