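test_that("stride length, time and velocity follow their definitions", {
  expect_equal(stride_length(c(0, 0), c(1.20, 0.10)), sqrt(1.20^2 + 0.10^2))
  expect_equal(stride_length(c(0.4, 0.2), c(0.4, 0.2)), 0)
  expect_equal(stride_length(c(0, 0), c(0, 0.5)), 0.5)

  expect_equal(stride_time(10.000, 11.100), 1.100)
  expect_equal(stride_time(0, 1 / 90), 1 / 90)
  expect_error(stride_time(2.0, 2.0), "strictly after")

  expect_equal(stride_velocity(sqrt(1.20^2 + 0.10^2), 1.100),
               sqrt(1.20^2 + 0.10^2) / 1.1)
  expect_equal(stride_velocity(0, 1), 0)
  expect_error(stride_velocity(1, 0), "positive")
})

test_that("stride width matches the printed formula and flags bad geometry", {
  # contralateral heel at the stride midline: SW is its lateral offset
  sw <- stride_width(c(1, 0), c(0.5, 0.12), SL = 1)
  expect_true(sw$valid)
  expect_equal(sw$SW, 0.12, tolerance = 1e-12)

  sw0 <- stride_width(c(1, 0), c(0.5, 0), SL = 1)
  expect_equal(sw0$SW, 0)

  bad <- stride_width(c(1, 0), c(0.9, 0), SL = 1)   # d = 0.1 < SL/2
  expect_false(bad$valid)
  expect_true(is.nan(bad$SW))
  expect_error(stride_width(c(1, 0), c(0.5, 0.1), SL = 0), "positive")
})

test_that("stride width equals the perpendicular-distance oracle on midpoint geometries", {
  set.seed(31)
  for (i in 1:100) {
    a <- runif(2, -2, 2)                      # previous same-foot HS
    dir <- runif(1, 0, 2 * pi)
    SL <- runif(1, 0.6, 1.6)
    b <- a + SL * c(cos(dir), sin(dir))       # current same-foot HS
    w <- runif(1, 0, 0.3)
    normal <- c(-sin(dir), cos(dir))
    p <- (a + b) / 2 + w * normal             # contralateral heel at the midpoint
    sw <- stride_width(b, p, SL)
    expect_true(sw$valid)
    expect_equal(sw$SW, point_line_distance(p, a, b), tolerance = 1e-9)
    expect_equal(sw$SW, w, tolerance = 1e-9)
  }
})

test_that("phase percentages partition the cycle and sum to 100", {
  expect_equal(phase_percentages(0.0, 0.66, 1.10), c(STC_pct = 60, SWC_pct = 40))
  expect_equal(phase_percentages(0.0, 0.55, 1.10), c(STC_pct = 50, SWC_pct = 50))
  set.seed(32)
  for (i in 1:50) {
    ts <- sort(runif(3, 0, 10))
    p <- phase_percentages(ts[1], ts[2], ts[3])
    expect_equal(sum(p), 100, tolerance = 1e-9)
  }
})

test_that("full feature tables reproduce the simulator's analytic truth", {
  trial <- noiseless_trial(n_strides = 8)
  res <- run_trial_pipeline(trial)
  feats <- res$features
  truth <- trial$truth_features
  expect_equal(nrow(feats), nrow(truth))
  expect_equal(feats$SL_m, truth$SL_m, tolerance = 1e-9)
  expect_equal(feats$ST_s, truth$ST_s, tolerance = 1e-9)
  expect_equal(feats$SV_mps, truth$SV_mps, tolerance = 1e-9)
  expect_true(all(feats$valid_SW))
  # internal consistency invariants
  expect_equal(feats$SV_mps * feats$ST_s, feats$SL_m, tolerance = 1e-9)
  expect_equal(feats$STC_pct + feats$SWC_pct, rep(100, nrow(feats)),
               tolerance = 1e-9)
})

test_that("features are invariant under rigid translation and time shift", {
  trial <- noiseless_trial(n_strides = 6)
  res <- run_trial_pipeline(trial)

  shift_series <- function(s, dxyz, dt) {
    s$t <- s$t + dt
    s$pos <- sweep(s$pos, 2, dxyz, `+`)
    s
  }
  trial2 <- trial
  trial2$left <- shift_series(trial$left, c(3, -2, 0.5), 10)
  trial2$right <- shift_series(trial$right, c(3, -2, 0.5), 10)
  res2 <- run_trial_pipeline(trial2)
  for (col in c("SL_m", "ST_s", "SW_m", "SV_mps", "STC_pct")) {
    expect_equal(res2$features[[col]], res$features[[col]], tolerance = 1e-9,
                 label = col)
  }
})

test_that("single-foot trials compute everything except stride width", {
  trial <- noiseless_trial(n_strides = 5)
  res <- suppressWarnings(run_gait_pipeline(
    left = trial$left, right = NULL, run_config(),
    heel_offset_left = trial$spec$heel_offset))
  expect_gt(nrow(res$features), 0L)
  expect_true(all(!res$features$valid_SW))
  expect_true(all(is.nan(res$features$SW_m)))
  expect_equal(res$features$ST_s, rep(trial$spec$ST_true, nrow(res$features)),
               tolerance = 1e-9)

  empty <- stride_features(NULL, NULL, matrix(0, 0, 2), matrix(0, 0, 2))
  expect_equal(nrow(empty), 0L)
})
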