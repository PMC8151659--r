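# Synthetic gait simulator: paired "VR tracker" and "reference" streams
# with analytic ground truth, emulating a subject walking a straight line
# while an instrumented walkway logs footfall events at its own rate and
# clock.

#' Specification of a synthetic gait trial
#'
#' Defaults describe comfortable self-selected adult walking: stride length
#' 1.25 m, stride time 1.1 s, stride width 0.10 m, 60% stance, foot
#' clearance peaks of 5 and 4 cm. The tracker samples at 90 Hz and the
#' reference device registers events on its own 120 Hz grid, optionally
#' shifted by a known clock offset.
#'
#' @param n_strides Strides per foot.
#' @param SL_true Stride length, meters.
#' @param ST_true Stride time, seconds.
#' @param SW_true Stride width, meters.
#' @param stance_fraction Stance duration as a fraction of the cycle
#'   (0-1 exclusive).
#' @param clearance_peak1,clearance_peak2 Heights of the toe-off and
#'   heel-strike clearance peaks, meters.
#' @param peak1_frac,peak2_frac Fractions of the swing excursion at which
#'   the two peaks occur (`0 < peak1_frac < peak2_frac < 1`).
#' @param valley_frac Height of the inter-peak saddle as a fraction of the
#'   lower peak (keeps the excursion in one piece above the detector's
#'   baseline band).
#' @param noise_sd_pos SD of i.i.d. Gaussian noise added to each tracker
#'   position axis, meters.
#' @param fs_vr Tracker sampling rate, Hz (default 90).
#' @param fs_ref Reference event grid rate, Hz (default 120).
#' @param clock_offset_s Known offset added to reference event times
#'   relative to the tracker clock, seconds.
#' @param heel_offset Tracker-frame heel offset used to derive tracker pose
#'   from heel trajectory, meters.
#' @param yaw_deg Constant tracker yaw about vertical, degrees.
#' @param walkway_length_m Walkway length, meters (default 6.10; a standard
#'   instrumented-walkway footprint, used by bounding-box examples).
#' @param seed Integer RNG seed, or `NULL`.
#' @return A list of class `synthetic_gait_spec`.
#' @export
synthetic_gait_spec <- function(n_strides = 20L,
                                SL_true = 1.25,
                                ST_true = 1.1,
                                SW_true = 0.10,
                                stance_fraction = 0.60,
                                clearance_peak1 = 0.05,
                                clearance_peak2 = 0.04,
                                peak1_frac = 0.2,
                                peak2_frac = 0.8,
                                valley_frac = 0.35,
                                noise_sd_pos = 0.003,
                                fs_vr = 90,
                                fs_ref = 120,
                                clock_offset_s = 0,
                                heel_offset = c(-0.15, 0.0, -0.08),
                                yaw_deg = 0,
                                walkway_length_m = 6.10,
                                seed = NULL) {
  stopifnot(n_strides >= 1,
            SL_true > 0, ST_true > 0, SW_true >= 0,
            stance_fraction > 0, stance_fraction < 1,
            clearance_peak1 > 0, clearance_peak2 > 0,
            peak1_frac > 0, peak1_frac < peak2_frac, peak2_frac < 1,
            valley_frac > 0, valley_frac < 1,
            noise_sd_pos >= 0, fs_vr > 0, fs_ref > 0,
            length(heel_offset) == 3L)
  # excursion must stay clear of the neighbouring stance floors
  W <- ST_true * (1 - stance_fraction) / (peak2_frac - peak1_frac)
  if (peak1_frac * W >= stance_fraction * ST_true ||
      (1 - peak2_frac) * W >= stance_fraction * ST_true) {
    stop("synthetic_gait_spec: clearance excursion overlaps the neighbouring stance phase; move peak fractions outward or increase stance_fraction")
  }
  structure(as.list(environment())[c(
    "n_strides", "SL_true", "ST_true", "SW_true", "stance_fraction",
    "clearance_peak1", "clearance_peak2", "peak1_frac", "peak2_frac",
    "valley_frac", "noise_sd_pos", "fs_vr", "fs_ref", "clock_offset_s",
    "heel_offset", "yaw_deg", "walkway_length_m", "seed")],
    class = "synthetic_gait_spec")
}

#' Vertical foot-clearance profile of one swing excursion
#'
#' A C1 curve on phase in [0, 1], zero at both ends, with exactly two
#' strict interior local maxima: height `clearance_peak1` at `peak1_frac`
#' (toe off) and `clearance_peak2` at `peak2_frac` (heel strike). The curve
#' is a low pedestal of height `valley_frac * min(peaks)` (half-cosine
#' ramps at the ends, flat in between) carrying two raised-cosine bumps
#' centred exactly on the peak phases. Each bump is locally symmetric about
#' its peak, so zero-phase low-pass filtering does not displace the peak
#' sample; peak locations and heights are analytically exact.
#'
#' @param phase Fraction of the excursion in `[0, 1]` (vectorized).
#' @param spec A [synthetic_gait_spec()].
#' @return Clearance in meters, same length as `phase`.
#' @export
vertical_profile <- function(phase, spec) {
  if (any(phase < 0 | phase > 1)) {
    stop("vertical_profile: phase must lie in [0, 1]")
  }
  c1 <- spec$peak1_frac
  c2 <- spec$peak2_frac
  h1 <- spec$clearance_peak1
  h2 <- spec$clearance_peak2
  v <- spec$valley_frac * min(h1, h2)
  d <- bump_halfwidth(spec)
  out <- numeric(length(phase))
  # pedestal: 0 -> v -> 0 with half-cosine ramps outside the bump supports
  ru <- c1 - d
  fu <- c2 + d
  i <- phase <= ru
  out[i] <- v * 0.5 * (1 - cos(pi * phase[i] / ru))
  i <- phase > ru & phase < fu
  out[i] <- v
  i <- phase >= fu
  out[i] <- v * 0.5 * (1 + cos(pi * (phase[i] - fu) / (1 - fu)))
  # symmetric raised-cosine bumps on top of the pedestal
  for (pk in list(c(c1, h1), c(c2, h2))) {
    i <- abs(phase - pk[1]) < d
    out[i] <- out[i] + (pk[2] - v) * 0.5 * (1 + cos(pi * (phase[i] - pk[1]) / d))
  }
  out
}

# half-width (in phase units) of the symmetric clearance bumps: stay inside
# [0, 1], keep the two bumps disjoint, and leave room for the pedestal ramps
bump_halfwidth <- function(spec) {
  min(0.75 * spec$peak1_frac,
      0.75 * (1 - spec$peak2_frac),
      (spec$peak2_frac - spec$peak1_frac) / 2)
}

#' Simulate a paired tracker / reference gait trial
#'
#' Constructs per-foot heel-strike times from the stride time with a 50%
#' inter-foot phase shift, toe offs at `HS + stance_fraction * ST`, heel X
#' advancing one stride length per stride (half-cosine swing displacement,
#' so the heel is stationary with zero velocity at every event), heel Y at
#' +/- half the stride width per foot, and the vertical channel from
#' [vertical_profile()] with the two peaks placed exactly at the TO and HS
#' instants. Tracker pose is derived by inverting the heel transformation
#' with `heel_offset` under a constant yaw, then corrupted with i.i.d.
#' Gaussian position noise. Reference events are the truth events snapped
#' to the `fs_ref` grid and shifted by `clock_offset_s`.
#'
#' The first heel strike of each foot precedes the first clearance
#' excursion (the subject is already walking when recording starts), so it
#' has no detectable waveform signature; truth and reference streams start
#' at each foot's first toe off, and a trial of N strides yields N - 1
#' complete cycles.
#'
#' @param spec A [synthetic_gait_spec()].
#' @return A list of class `synthetic_trial`: `left`, `right`
#'   ([tracker_series] with noisy tracker poses), `reference` (event data
#'   frame on the reference grid/clock), `truth_events` (exact event times
#'   with nearest tracker-grid sample indices), `truth_features`
#'   (analytic per-stride features), and `spec`.
#' @export
simulate_trial <- function(spec) {
  stopifnot(inherits(spec, "synthetic_gait_spec"))
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(spec$seed)
  }
  ST <- spec$ST_true
  SL <- spec$SL_true
  stance <- spec$stance_fraction * ST
  swing <- ST - stance
  W <- swing / (spec$peak2_frac - spec$peak1_frac)   # excursion window length, s
  t0 <- 0.5 + spec$peak1_frac * W                    # first right HS; keeps excursions interior
  n <- spec$n_strides

  foot_timing <- function(shift) {
    hs <- t0 + shift + (0:n) * ST
    to <- hs[1:n] + stance
    list(hs = hs, to = to)
  }
  right <- foot_timing(0)
  left <- foot_timing(0.5 * ST)
  t_end <- max(left$hs, right$hs) + stance + 0.5
  nt <- floor(t_end * spec$fs_vr)
  tg <- (0:nt) / spec$fs_vr

  yaw <- spec$yaw_deg * pi / 180
  quat <- c(cos(yaw / 2), 0, 0, sin(yaw / 2))   # rotation about +Z

  build_foot <- function(tm, x_hs0, y_heel, foot) {
    hs <- tm$hs
    to <- tm$to
    x_hs <- x_hs0 + (0:n) * SL
    # heel trajectories on the tracker grid
    x <- rep(x_hs[1], length(tg))
    z <- numeric(length(tg))
    for (i in seq_len(n)) {
      # swing i: TO[i] -> HS[i+1]; half-cosine forward displacement
      inswing <- tg > to[i] & tg < hs[i + 1]
      u <- (tg[inswing] - to[i]) / swing
      x[inswing] <- x_hs[i] + SL * 0.5 * (1 - cos(pi * u))
      x[tg >= hs[i + 1]] <- x_hs[i + 1]
      # clearance excursion with peaks exactly at TO[i] and HS[i+1]
      w0 <- to[i] - spec$peak1_frac * W
      inwin <- tg >= w0 & tg <= w0 + W
      z[inwin] <- z[inwin] + vertical_profile((tg[inwin] - w0) / W, spec)
    }
    heel <- cbind(x, rep(y_heel, length(tg)), z)
    quat_mat <- matrix(quat, nrow = length(tg), ncol = 4L, byrow = TRUE)
    pos_tracker <- heel - quat_rotate(quat_mat, spec$heel_offset)
    if (spec$noise_sd_pos > 0) {
      pos_tracker <- pos_tracker +
        matrix(stats::rnorm(length(pos_tracker), 0, spec$noise_sd_pos),
               ncol = 3L)
    }
    series <- tracker_series(foot, tg, pos_tracker, quat_mat, rate_hz = spec$fs_vr)

    # truth: events from TO[1] on (the opening HS has no waveform support)
    ev_t <- as.numeric(rbind(to, hs[-1]))
    ev_k <- rep(c("TO", "HS"), n)
    truth <- data.frame(kind = ev_k, foot = foot, t = ev_t,
                        idx = as.integer(round(ev_t * spec$fs_vr)) + 1L)
    # analytic per-stride features (strides 2..n have a full cycle)
    feats <- if (n >= 2L) data.frame(
      foot = foot,
      t_hs_prev = hs[2:n], t_to = to[2:n], t_hs_cur = hs[3:(n + 1)],
      SL_m = SL, ST_s = ST, SW_m = spec$SW_true,
      SV_mps = SL / ST,
      STC_pct = 100 * spec$stance_fraction,
      SWC_pct = 100 * (1 - spec$stance_fraction),
      valid_SW = TRUE) else NULL
    list(series = series, truth = truth, feats = feats, heel = heel)
  }

  r <- build_foot(right, x_hs0 = 0, y_heel = -spec$SW_true / 2, foot = "right")
  l <- build_foot(left, x_hs0 = 0.5 * SL, y_heel = +spec$SW_true / 2, foot = "left")

  truth_events <- rbind(r$truth, l$truth)
  truth_events <- truth_events[order(truth_events$foot, truth_events$t), ]
  rownames(truth_events) <- NULL

  reference <- truth_events[, c("kind", "foot", "t")]
  reference$t <- snap_event_times(reference$t, spec$fs_ref) + spec$clock_offset_s
  reference <- reference[order(reference$foot, reference$t), ]
  rownames(reference) <- NULL

  truth_features <- rbind(r$feats, l$feats)
  if (!is.null(truth_features)) {
    truth_features <- truth_features[order(truth_features$t_hs_cur), ]
    rownames(truth_features) <- NULL
  }

  structure(list(left = l$series, right = r$series,
                 reference = structure(reference, rate_hz = spec$fs_ref,
                                       class = c("gait_events", "data.frame")),
                 truth_events = truth_events,
                 truth_features = truth_features,
                 spec = spec),
            class = "synthetic_trial")
}
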