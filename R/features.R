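# Spatiotemporal stride features, computed per gait cycle from heel
# positions at the detected events. Features are 2D (horizontal plane):
# the reference walkway only provides 2D displacement, so the comparison
# is defined there.

#' Stride length
#'
#' Horizontal Euclidean distance between the heel positions of two
#' consecutive same-foot heel strikes.
#'
#' @param heel_prev_xy,heel_cur_xy Heel XY positions (anteroposterior,
#'   mediolateral) at the previous and current same-foot HS, meters.
#' @return Stride length in meters.
#' @export
stride_length <- function(heel_prev_xy, heel_cur_xy) {
  d <- as.numeric(heel_cur_xy) - as.numeric(heel_prev_xy)
  stopifnot(length(d) == 2L, all(is.finite(d)))
  sqrt(sum(d^2))
}

#' Stride time
#'
#' @param t_hs_prev,t_hs_cur Times of two consecutive same-foot heel
#'   strikes, seconds.
#' @return Stride time in seconds.
#' @export
stride_time <- function(t_hs_prev, t_hs_cur) {
  if (t_hs_cur <= t_hs_prev) {
    stop("stride_time: current HS must come strictly after the previous HS")
  }
  t_hs_cur - t_hs_prev
}

#' Stride width
#'
#' Perpendicular distance between the line through two consecutive
#' same-foot heel strikes and the contralateral heel at its intervening
#' heel strike, computed as `sqrt(d^2 - (SL/2)^2)` where `d` is the
#' distance between the current same-foot HS heel and the contralateral HS
#' heel. The formula assumes the contralateral heel's projection onto the
#' stride line is its midpoint (symmetric gait); if the radicand is
#' negative the geometry violates that assumption and the width is
#' returned as `NaN` with `valid = FALSE` rather than clamped.
#'
#' @param heel_cur_xy Same-foot heel XY at the current (cycle-closing) HS.
#' @param heel_contra_xy Contralateral heel XY at its HS inside the cycle.
#' @param SL Stride length of the cycle, meters (> 0).
#' @return `list(SW = meters, valid = flag)`.
#' @export
stride_width <- function(heel_cur_xy, heel_contra_xy, SL) {
  if (SL <= 0) stop("stride_width: SL must be positive")
  d2 <- sum((as.numeric(heel_cur_xy) - as.numeric(heel_contra_xy))^2)
  rad <- d2 - (SL / 2)^2
  if (rad < 0) list(SW = NaN, valid = FALSE) else list(SW = sqrt(rad), valid = TRUE)
}

#' Stride velocity
#'
#' @param SL Stride length, meters.
#' @param ST Stride time, seconds (> 0).
#' @return Stride velocity in m/s (`SL / ST`).
#' @export
stride_velocity <- function(SL, ST) {
  if (ST <= 0) stop("stride_velocity: ST must be positive")
  SL / ST
}

#' Stance and swing percentages of a gait cycle
#'
#' Stance runs from the opening HS to the TO, swing from the TO to the
#' closing HS; each is expressed as a percentage of the full cycle. The two
#' percentages are complementary: they sum to exactly 100.
#'
#' @param t_hs_prev,t_to,t_hs_cur Event times of one cycle, seconds, with
#'   `t_hs_prev < t_to < t_hs_cur`.
#' @return `c(STC_pct, SWC_pct)`.
#' @export
phase_percentages <- function(t_hs_prev, t_to, t_hs_cur) {
  if (!(t_hs_prev < t_to && t_to < t_hs_cur)) {
    stop("phase_percentages: need t_hs_prev < t_to < t_hs_cur")
  }
  cyc <- t_hs_cur - t_hs_prev
  stc <- 100 * (t_to - t_hs_prev) / cyc
  c(STC_pct = stc, SWC_pct = 100 - stc)
}

#' Per-stride features for both feet
#'
#' Computes stride length, time, width, velocity and stance/swing
#' percentages for every segmented cycle of both feet. Heel positions at an
#' event are taken at the event's sample index (events are defined on
#' samples; no interpolation). Stride width pairs the cycle-closing
#' same-foot HS with the contralateral HS whose time falls strictly inside
#' the cycle; if no such contralateral HS exists (e.g. a single-foot
#' trial), SW is invalid for that stride.
#'
#' @param cycles_left,cycles_right `gait_cycles` data frames (either may be
#'   empty / `NULL`).
#' @param heel_left_xy,heel_right_xy `n x 2` matrices of heel XY positions
#'   for each foot's full series, meters.
#' @param events_left,events_right Event data frames (with `t`, `kind`,
#'   `idx`) used to locate contralateral heel strikes. Defaults to the HS
#'   events implied by the contralateral cycles.
#' @return A `data.frame` with one row per stride, columns `foot`,
#'   `t_hs_prev`, `t_to`, `t_hs_cur`, `SL_m`, `ST_s`, `SW_m`, `SV_mps`,
#'   `STC_pct`, `SWC_pct`, `valid_SW`, ordered by `t_hs_cur`.
#' @export
stride_features <- function(cycles_left, cycles_right,
                            heel_left_xy, heel_right_xy,
                            events_left = NULL, events_right = NULL) {
  hs_from_cycles <- function(cycles) {
    if (is.null(cycles) || !nrow(cycles)) {
      return(data.frame(t = numeric(0), idx = integer(0)))
    }
    hs <- unique(rbind(
      data.frame(t = cycles$t_hs_prev, idx = cycles$idx_hs_prev),
      data.frame(t = cycles$t_hs_cur, idx = cycles$idx_hs_cur)))
    hs[order(hs$t), , drop = FALSE]
  }
  hs_events <- function(events, cycles) {
    if (is.null(events)) return(hs_from_cycles(cycles))
    ev <- as.data.frame(events)
    ev <- ev[ev$kind == "HS", c("t", "idx"), drop = FALSE]
    ev[order(ev$t), , drop = FALSE]
  }
  one_foot <- function(cycles, heel_xy, contra_hs, contra_heel_xy, foot) {
    if (is.null(cycles) || !nrow(cycles)) return(NULL)
    heel_xy <- as.matrix(heel_xy)
    contra_heel_xy <- as.matrix(contra_heel_xy)
    out <- vector("list", nrow(cycles))
    for (i in seq_len(nrow(cycles))) {
      cy <- cycles[i, ]
      p_prev <- heel_xy[cy$idx_hs_prev, ]
      p_cur <- heel_xy[cy$idx_hs_cur, ]
      SL <- stride_length(p_prev, p_cur)
      ST <- stride_time(cy$t_hs_prev, cy$t_hs_cur)
      ph <- phase_percentages(cy$t_hs_prev, cy$t_to, cy$t_hs_cur)
      SW <- NaN
      valid <- FALSE
      if (SL > 0 && nrow(contra_hs)) {
        inb <- which(contra_hs$t > cy$t_hs_prev & contra_hs$t < cy$t_hs_cur)
        if (length(inb)) {
          # nearest to mid-cycle if the stream carries spurious extras
          mid <- (cy$t_hs_prev + cy$t_hs_cur) / 2
          j <- inb[which.min(abs(contra_hs$t[inb] - mid))]
          sw <- stride_width(p_cur, contra_heel_xy[contra_hs$idx[j], ], SL)
          SW <- sw$SW
          valid <- sw$valid
        }
      }
      out[[i]] <- data.frame(
        foot = cy$foot, t_hs_prev = cy$t_hs_prev, t_to = cy$t_to,
        t_hs_cur = cy$t_hs_cur, SL_m = SL, ST_s = ST, SW_m = SW,
        SV_mps = stride_velocity(SL, ST),
        STC_pct = ph[["STC_pct"]], SWC_pct = ph[["SWC_pct"]],
        valid_SW = valid)
    }
    do.call(rbind, out)
  }
  res <- rbind(
    one_foot(cycles_left, heel_left_xy,
             hs_events(events_right, cycles_right), heel_right_xy, "left"),
    one_foot(cycles_right, heel_right_xy,
             hs_events(events_left, cycles_left), heel_left_xy, "right"))
  if (is.null(res)) {
    res <- data.frame(foot = character(0), t_hs_prev = numeric(0),
                      t_to = numeric(0), t_hs_cur = numeric(0),
                      SL_m = numeric(0), ST_s = numeric(0), SW_m = numeric(0),
                      SV_mps = numeric(0), STC_pct = numeric(0),
                      SWC_pct = numeric(0), valid_SW = logical(0))
  }
  res <- res[order(res$t_hs_cur), , drop = FALSE]
  rownames(res) <- NULL
  res
}
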