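# Independent oracles and small fixture builders used across the suite.

# Exhaustive optimal one-to-one event matching: maximize the number of
# matched pairs within tolerance, tie-break by minimum total |dt|.
# Recursion over reference events; feasible for <= 8 events per side.
brute_force_match <- function(detected, reference, tol_s) {
  nd <- length(detected)
  nr <- length(reference)
  best <- list(n = -1L, cost = Inf, pairs = NULL)
  recurse <- function(ri, used_d, pairs, cost) {
    if (ri > nr) {
      n <- nrow(pairs)
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost, pairs = pairs)
      }
      return(invisible())
    }
    # skip this reference event
    recurse(ri + 1L, used_d, pairs, cost)
    for (di in seq_len(nd)) {
      if (!used_d[di] && abs(detected[di] - reference[ri]) <= tol_s) {
        used_d2 <- used_d
        used_d2[di] <- TRUE
        recurse(ri + 1L, used_d2,
                rbind(pairs, data.frame(det_idx = di, ref_idx = ri)),
                cost + abs(detected[di] - reference[ri]))
      }
    }
  }
  recurse(1L, logical(nd), data.frame(det_idx = integer(0), ref_idx = integer(0)), 0)
  best
}

# Gait-like random matching instance: reference events separated by more
# than twice the tolerance (as in real event streams, where inter-event
# gaps are hundreds of ms against a 33 ms window), detections jittered
# around a random subset, plus occasional spurious detections.
random_match_instance <- function(tol_s = 1 / 30) {
  nr <- sample(1:8, 1)
  gaps <- stats::runif(nr, 2.2 * tol_s, 0.6)
  reference <- cumsum(gaps)
  keep <- stats::runif(nr) < 0.85
  detected <- reference[keep] + stats::runif(sum(keep), -1.4 * tol_s, 1.4 * tol_s)
  if (stats::runif(1) < 0.3) {
    detected <- c(detected, max(reference) + stats::runif(1, 3 * tol_s, 1))
  }
  list(detected = sort(detected), reference = reference)
}

# Perpendicular distance from point p to the infinite line through a and b.
point_line_distance <- function(p, a, b) {
  ab <- b - a
  ap <- p - a
  abs(ab[1] * ap[2] - ab[2] * ap[1]) / sqrt(sum(ab^2))
}

# Default noiseless synthetic trial used by several tests.
noiseless_trial <- function(n_strides = 10, ...) {
  simulate_trial(synthetic_gait_spec(n_strides = n_strides, noise_sd_pos = 0,
                                     clock_offset_s = 0, seed = 7, ...))
}

run_trial_pipeline <- function(trial, config = run_config()) {
  suppressWarnings(run_gait_pipeline(
    trial$left, trial$right, config,
    heel_offset_left = trial$spec$heel_offset,
    heel_offset_right = trial$spec$heel_offset))
}
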