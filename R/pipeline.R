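# End-to-end pipeline: filter -> heel transform -> detrend(z) -> detect ->
# segment -> (bbox gate) -> features, with stage counts logged, plus the
# validation wrapper against a reference stream.

#' Process one foot's tracker series into events, cycles and heel positions
#'
#' Stages: zero-phase low-pass filtering of all three position axes, rigid
#' sensor-to-heel transformation, linear detrending of the vertical heel
#' channel, double-peak event detection, cycle segmentation, optional
#' walkway bounding-box gating.
#'
#' @param series A [tracker_series].
#' @param heel_offset Tracker-frame heel offset, meters.
#' @param config A [run_config()].
#' @return A list: `events`, `cycles`, `heel_xy` (n x 2 matrix of heel X/Y
#'   for the full series), `log` (stage counts).
#' @export
process_foot <- function(series, heel_offset, config = run_config()) {
  stopifnot(inherits(series, "tracker_series"))
  fs <- series$rate_hz
  pos_f <- lowpass_zero_phase(series$pos, fs,
                              cutoff_hz = config$filter_cutoff_hz,
                              order = config$filter_order)
  filt <- series
  filt$pos <- pos_f
  heel <- heel_series(filt, heel_offset)
  z <- detrend_linear(heel$pos[, 3])
  events <- detect_events(z, heel$t, series$foot, config$detector)
  cycles <- segment_cycles(events,
                           min_cycle_s = config$detector$min_cycle_s,
                           max_cycle_s = config$detector$max_cycle_s)
  n_before <- nrow(cycles)
  heel_xy <- heel$pos[, 1:2, drop = FALSE]
  cycles <- exclude_out_of_bounds(cycles, heel_xy, config$walkway_bbox)
  list(events = events,
       cycles = cycles,
       heel_xy = heel_xy,
       log = list(foot = series$foot,
                  n_samples = length(series$t),
                  n_events = nrow(events),
                  n_cycles = nrow(cycles),
                  n_cycles_out_of_bounds = n_before - nrow(cycles)))
}

#' Run the full gait pipeline on both feet
#'
#' @param left,right [tracker_series] for each foot (either may be `NULL`).
#' @param config A [run_config()].
#' @param heel_offset_left,heel_offset_right Tracker-frame heel offsets,
#'   meters. Default `c(0, 0, 0)` (tracker position used directly).
#' @return A list of class `gait_pipeline_result`: `events` (both feet,
#'   time-ordered), `features` (per-stride table), per-foot `left`/`right`
#'   results from [process_foot()], and `log`.
#' @export
run_gait_pipeline <- function(left = NULL, right = NULL,
                              config = run_config(),
                              heel_offset_left = c(0, 0, 0),
                              heel_offset_right = c(0, 0, 0)) {
  if (is.null(left) && is.null(right)) {
    stop("run_gait_pipeline: need at least one foot's series")
  }
  L <- if (!is.null(left)) process_foot(left, heel_offset_left, config) else NULL
  R <- if (!is.null(right)) process_foot(right, heel_offset_right, config) else NULL
  features <- stride_features(
    cycles_left = if (!is.null(L)) L$cycles else NULL,
    cycles_right = if (!is.null(R)) R$cycles else NULL,
    heel_left_xy = if (!is.null(L)) L$heel_xy else matrix(0, 0, 2),
    heel_right_xy = if (!is.null(R)) R$heel_xy else matrix(0, 0, 2),
    events_left = if (!is.null(L)) L$events else NULL,
    events_right = if (!is.null(R)) R$events else NULL)
  events <- rbind(if (!is.null(L)) L$events else NULL,
                  if (!is.null(R)) R$events else NULL)
  if (!is.null(events)) {
    events <- events[order(events$t), ]
    rownames(events) <- NULL
  }
  structure(list(events = events, features = features,
                 left = L, right = R,
                 log = list(left = if (!is.null(L)) L$log else NULL,
                            right = if (!is.null(R)) R$log else NULL,
                            n_strides = nrow(features))),
            class = "gait_pipeline_result")
}

#' Validate a pipeline result against a reference stream
#'
#' Convenience wrapper building a [validation_report()] from a pipeline
#' result, a reference event table and (optionally) a reference feature
#' table.
#'
#' @param result A `gait_pipeline_result`.
#' @param reference_events Reference event data frame (`kind`, `foot`, `t`).
#' @param reference_features Optional reference per-stride feature table.
#' @param config A [run_config()].
#' @return A `validation_report`.
#' @export
validate_pipeline <- function(result, reference_events,
                              reference_features = NULL,
                              config = run_config()) {
  validation_report(result$events, reference_events,
                    vr_features = if (is.null(reference_features)) NULL else result$features,
                    ref_features = reference_features,
                    config = config)
}
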