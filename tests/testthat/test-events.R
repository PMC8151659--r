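test_that("degenerate signals yield empty event lists with warnings", {
  t <- (0:499) / 90
  expect_warning(ev <- detect_events(rep(0, 500), t, "left"), "no events")
  expect_equal(nrow(ev), 0L)

  # one isolated single-peaked bump: excursion discarded
  z <- numeric(500)
  z[200:260] <- 0.05 * sin(pi * (0:60) / 60)
  expect_warning(ev <- detect_events(z, t, "left"), "discarded")
  expect_equal(nrow(ev), 0L)
})

test_that("noiseless synthetic trials are recovered on the exact samples", {
  trial <- noiseless_trial(n_strides = 8)
  res <- run_trial_pipeline(trial)
  expect_equal(nrow(res$events), nrow(trial$truth_events))
  m <- merge(res$events, trial$truth_events, by = c("kind", "foot", "idx"))
  expect_equal(nrow(m), nrow(trial$truth_events))  # every event on its truth sample
  # detector output alternates TO/HS starting at TO per foot
  for (f in c("left", "right")) {
    k <- res$events$kind[res$events$foot == f]
    expect_equal(k[1], "TO")
    expect_true(all(k[-1] != k[-length(k)]))
  }
})

test_that("detection is deterministic", {
  trial <- simulate_trial(synthetic_gait_spec(n_strides = 5, seed = 99))
  z <- detrend_linear(lowpass_zero_phase(trial$left$pos[, 3], 90))
  e1 <- suppressWarnings(detect_events(z, trial$left$t, "left"))
  e2 <- suppressWarnings(detect_events(z, trial$left$t, "left"))
  expect_identical(e1, e2)
})

test_that("cycle segmentation follows the HS-TO-HS triple rule", {
  ev <- data.frame(kind = c("TO", "HS", "TO", "HS"), foot = "left",
                   t = c(1.0, 1.4, 2.1, 2.5), idx = 1:4)
  cy <- segment_cycles(ev)
  expect_equal(nrow(cy), 1L)  # leading TO has no preceding HS
  expect_equal(c(cy$t_hs_prev, cy$t_to, cy$t_hs_cur), c(1.4, 2.1, 2.5))

  ev <- data.frame(kind = c("HS", "TO", "HS", "TO", "HS"), foot = "left",
                   t = c(1.0, 1.6, 2.1, 2.7, 3.2), idx = 1:5)
  expect_equal(nrow(segment_cycles(ev)), 2L)

  # stride duration out of bounds is dropped with a warning
  ev <- data.frame(kind = c("HS", "TO", "HS"), foot = "left",
                   t = c(1.0, 2.6, 4.0), idx = 1:3)
  expect_warning(cy <- segment_cycles(ev, max_cycle_s = 2.5), "dropped")
  expect_equal(nrow(cy), 0L)

  expect_equal(nrow(segment_cycles(ev[0, ])), 0L)
})

test_that("N strides give N - 1 cycles and bbox gating excludes turnarounds", {
  n <- 6
  trial <- noiseless_trial(n_strides = n)
  res <- run_trial_pipeline(trial)
  expect_equal(nrow(res$left$cycles), n - 1L)
  expect_equal(nrow(res$right$cycles), n - 1L)

  # a box covering half the walk keeps only the cycles inside it
  cy <- res$right$cycles
  xs <- res$right$heel_xy[cy$idx_hs_cur, 1]
  box <- c(-1, stats::median(xs), -0.5, 0.5)
  kept <- exclude_out_of_bounds(cy, res$right$heel_xy, box)
  expect_lt(nrow(kept), nrow(cy))
  expect_gt(nrow(kept), 0L)
  expect_true(all(res$right$heel_xy[kept$idx_hs_cur, 1] <= box[2]))

  # boundary is closed: a cycle whose HS sits exactly on the edge is kept
  x_edge <- res$right$heel_xy[cy$idx_hs_cur[1], 1]
  box2 <- c(-1, x_edge, -0.5, 0.5)
  kept2 <- exclude_out_of_bounds(cy[1, ], res$right$heel_xy, box2)
  expect_equal(nrow(kept2), 1L)

  # absent bbox is the identity
  expect_equal(nrow(exclude_out_of_bounds(cy, res$right$heel_xy, NULL)), nrow(cy))
})

test_that("detected events never contain two consecutive same-kind events", {
  set.seed(21)
  for (i in 1:5) {
    spec <- synthetic_gait_spec(n_strides = 4,
                                ST_true = runif(1, 0.9, 1.3),
                                noise_sd_pos = runif(1, 0, 0.004),
                                seed = sample.int(1e6, 1))
    trial <- simulate_trial(spec)
    z <- detrend_linear(lowpass_zero_phase(trial$right$pos[, 3], 90))
    ev <- suppressWarnings(detect_events(z, trial$right$t, "right"))
    if (nrow(ev) >= 2L) {
      expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
    }
    expect_equal(ev$t, trial$right$t[ev$idx])  # t == series.t[idx]
  }
})
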