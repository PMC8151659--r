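# Gait-event detection from the vertical foot-clearance waveform.
#
# During each swing the (filtered, detrended) vertical trajectory of a
# foot-mounted tracker traces a double-peaked excursion above the stance
# baseline: the first peak marks toe off (the foot lifting off), the second
# heel strike (the foot reaching the ground again). Events are the peak
# samples; consecutive HS..TO..HS triples define gait cycles.

#' Detector parameters
#'
#' @param min_prominence Minimum peak prominence in meters (default 0.01:
#'   foot clearance is multi-centimeter, so sub-centimeter wiggles are
#'   sensor jitter).
#' @param min_peak_separation_s Minimum time between retained peaks in
#'   seconds (default 0.10: double peaks closer than 100 ms are jitter).
#' @param min_cycle_s,max_cycle_s Plausible stride-duration bounds in
#'   seconds (defaults 0.4 and 2.5); candidate cycles outside the bounds
#'   are dropped.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(min_prominence = 0.01,
                            min_peak_separation_s = 0.10,
                            min_cycle_s = 0.4,
                            max_cycle_s = 2.5) {
  stopifnot(min_prominence > 0, min_peak_separation_s > 0,
            min_cycle_s > 0, max_cycle_s > min_cycle_s)
  structure(list(min_prominence = min_prominence,
                 min_peak_separation_s = min_peak_separation_s,
                 min_cycle_s = min_cycle_s,
                 max_cycle_s = max_cycle_s),
            class = "detector_params")
}

# Local maxima of z (indices). Plateaus count once, at their first sample.
local_maxima <- function(z) {
  n <- length(z)
  if (n < 3L) return(integer(0))
  d <- diff(z)
  # strip zero steps by carrying the previous sign (plateau handling)
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  which(diff(s) < 0) + 1L
}

# Prominence of each peak within the segment: height above the higher of
# the two bounding minima (bounds at a taller sample or the segment edge).
peak_prominence <- function(z, peaks) {
  vapply(peaks, function(p) {
    left <- p
    lo_l <- z[p]
    i <- p
    while (i > 1L && z[i - 1L] <= z[p]) {
      i <- i - 1L
      lo_l <- min(lo_l, z[i])
    }
    if (i == 1L) lo_l <- min(lo_l, z[1L])
    lo_r <- z[p]
    i <- p
    nz <- length(z)
    while (i < nz && z[i + 1L] <= z[p]) {
      i <- i + 1L
      lo_r <- min(lo_r, z[i])
    }
    if (i == nz) lo_r <- min(lo_r, z[nz])
    z[p] - max(lo_l, lo_r)
  }, numeric(1))
}

#' Detect toe-off and heel-strike events
#'
#' Operates on the preprocessed (low-pass filtered, linearly detrended)
#' vertical channel. Swing excursions are maximal runs of samples above a
#' baseline band of half `min_prominence` above the stance floor, which is
#' estimated robustly as the lower quartile of the signal (after
#' detrending, the foot is flat on the ground for well over a quarter of
#' the recording, so the lower quartile sits on the stance plateau
#' regardless of how much of each cycle the clearance excursion occupies). Within each excursion, local maxima with prominence at least
#' `min_prominence` and pairwise separation at least
#' `min_peak_separation_s` are retained; an excursion with exactly two such
#' peaks contributes a TO (earlier peak) and an HS (later peak), any other
#' count discards the excursion with a warning. Excursions touching the
#' first or last sample (partial swings at the trial edges) are discarded.
#'
#' @param z Preprocessed vertical signal, meters.
#' @param t Timestamps in seconds, same length as `z`.
#' @param foot `"left"` or `"right"`.
#' @param params A [detector_params()] list.
#' @return A `data.frame` (class `gait_events`) with columns `kind`
#'   (`"TO"`/`"HS"`, alternating, starting at TO), `foot`, `t`, `idx`
#'   (sample index into the series); `t == t[idx]` always.
#' @export
detect_events <- function(z, t, foot, params = detector_params()) {
  stopifnot(length(z) == length(t))
  foot <- match.arg(foot, c("left", "right"))
  empty <- structure(
    data.frame(kind = character(0), foot = character(0),
               t = numeric(0), idx = integer(0)),
    class = c("gait_events", "data.frame"))
  n <- length(z)
  if (n < 3L) {
    warning("detect_events: signal too short; no events")
    return(empty)
  }
  baseline <- as.numeric(stats::quantile(z, 0.25, names = FALSE))
  above <- z > baseline + 0.5 * params$min_prominence
  if (!any(above)) {
    warning("detect_events: no samples above the baseline band; no events")
    return(empty)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  # drop partial excursions touching the trial edges
  keep <- seg[, 1] > 1L & seg[, 2] < n
  seg <- seg[keep, , drop = FALSE]

  kinds <- character(0)
  idxs <- integer(0)
  n_discarded <- 0L
  for (s in seq_len(nrow(seg))) {
    i0 <- seg[s, 1]
    i1 <- seg[s, 2]
    zz <- z[i0:i1]
    pk <- local_maxima(zz)
    if (length(pk)) {
      prom <- peak_prominence(zz, pk)
      pk <- pk[prom >= params$min_prominence]
    }
    if (length(pk) > 1L) {
      # enforce separation: keep taller peaks first
      ord <- order(zz[pk], decreasing = TRUE)
      kept <- integer(0)
      for (p in pk[ord]) {
        if (!length(kept) || all(abs(t[i0 + p - 1L] - t[i0 + kept - 1L]) >= params$min_peak_separation_s)) {
          kept <- c(kept, p)
        }
      }
      pk <- sort(kept)
    }
    if (length(pk) == 2L) {
      kinds <- c(kinds, "TO", "HS")
      idxs <- c(idxs, i0 + pk - 1L)
    } else {
      n_discarded <- n_discarded + 1L
    }
  }
  if (n_discarded > 0L) {
    warning(sprintf("detect_events (%s foot): discarded %d swing excursion(s) without exactly 2 qualifying peaks",
                    foot, n_discarded))
  }
  if (!length(idxs)) {
    if (n_discarded == 0L) warning("detect_events: fewer than 2 qualifying peaks; no events")
    return(empty)
  }
  structure(
    data.frame(kind = kinds, foot = foot, t = t[idxs], idx = idxs),
    class = c("gait_events", "data.frame"))
}

#' Segment alternating events into gait cycles
#'
#' Every consecutive `(HS, TO, HS)` triple of a time-ordered single-foot
#' event list becomes one gait cycle (stance from the first HS to the TO,
#' swing from the TO to the closing HS), provided the stride duration lies
#' within `[min_cycle_s, max_cycle_s]`; out-of-bound candidates are dropped
#' with a warning. The leading TO of a trial has no preceding HS and opens
#' no cycle, so a trial of N strides yields N - 1 cycles.
#'
#' @param events Time-ordered single-foot event data frame (columns `kind`,
#'   `foot`, `t`, optionally `idx`).
#' @param min_cycle_s,max_cycle_s Stride-duration bounds in seconds.
#' @return A `data.frame` (class `gait_cycles`) with columns `foot`,
#'   `t_hs_prev`, `t_to`, `t_hs_cur` and, when `idx` is available,
#'   `idx_hs_prev`, `idx_to`, `idx_hs_cur`.
#' @export
segment_cycles <- function(events, min_cycle_s = 0.4, max_cycle_s = 2.5) {
  ev <- as.data.frame(events)
  has_idx <- "idx" %in% names(ev)
  empty <- data.frame(foot = character(0), t_hs_prev = numeric(0),
                      t_to = numeric(0), t_hs_cur = numeric(0),
                      idx_hs_prev = integer(0), idx_to = integer(0),
                      idx_hs_cur = integer(0))
  class(empty) <- c("gait_cycles", "data.frame")
  if (nrow(ev) < 3L) return(empty)
  if (length(unique(ev$foot)) > 1L) stop("segment_cycles: events must be from a single foot")
  if (is.unsorted(ev$t, strictly = TRUE)) stop("segment_cycles: events must be strictly time-ordered")
  rows <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(ev) - 2L)) {
    if (ev$kind[i] == "HS" && ev$kind[i + 1L] == "TO" && ev$kind[i + 2L] == "HS") {
      dur <- ev$t[i + 2L] - ev$t[i]
      if (dur >= min_cycle_s && dur <= max_cycle_s) {
        rows[[length(rows) + 1L]] <- data.frame(
          foot = ev$foot[i],
          t_hs_prev = ev$t[i], t_to = ev$t[i + 1L], t_hs_cur = ev$t[i + 2L],
          idx_hs_prev = if (has_idx) ev$idx[i] else NA_integer_,
          idx_to = if (has_idx) ev$idx[i + 1L] else NA_integer_,
          idx_hs_cur = if (has_idx) ev$idx[i + 2L] else NA_integer_)
      } else {
        n_dropped <- n_dropped + 1L
      }
    }
  }
  if (n_dropped > 0L) {
    warning(sprintf("segment_cycles: dropped %d cycle(s) with duration outside [%.2f, %.2f] s",
                    n_dropped, min_cycle_s, max_cycle_s))
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gait_cycles", "data.frame")
  out
}

#' Keep cycles whose heel strikes fall inside the walkway
#'
#' Turnarounds happen off the walkway; cycles whose opening and closing
#' heel-strike heel positions are not both inside the bounding box (closed
#' interval on every edge) are excluded. With `bbox = NULL` all cycles are
#' kept.
#'
#' @param cycles A `gait_cycles` data frame carrying `idx_hs_prev` /
#'   `idx_hs_cur`.
#' @param heel_xy `n x 2` matrix of heel X (anteroposterior) and Y
#'   (mediolateral) positions for the full series, meters.
#' @param bbox `c(x_min, x_max, y_min, y_max)` in meters, or `NULL`.
#' @return The filtered `gait_cycles` data frame.
#' @export
exclude_out_of_bounds <- function(cycles, heel_xy, bbox = NULL) {
  if (is.null(bbox) || !nrow(cycles)) return(cycles)
  stopifnot(length(bbox) == 4L)
  heel_xy <- as.matrix(heel_xy)
  inside <- function(idx) {
    x <- heel_xy[idx, 1]
    y <- heel_xy[idx, 2]
    x >= bbox[1] & x <= bbox[2] & y >= bbox[3] & y <= bbox[4]
  }
  keep <- inside(cycles$idx_hs_prev) & inside(cycles$idx_hs_cur)
  out <- cycles[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
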