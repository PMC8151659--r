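#' Construct a tracker pose series
#'
#' A `tracker_series` holds the timestamped world-frame pose stream of one
#' foot-mounted tracker: position in meters on axes X = anteroposterior
#' (forward-positive), Y = mediolateral (left-positive), Z = vertical
#' (up-positive), and a unit quaternion (scalar-first, world-from-tracker)
#' per sample.
#'
#' @param foot `"left"` or `"right"`.
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param pos Numeric matrix, one row per sample, columns X, Y, Z in meters.
#' @param quat Numeric matrix, one row per sample, columns qw, qx, qy, qz
#'   (scalar first). Each row must have unit norm within `1e-6`.
#' @param rate_hz Nominal sampling frequency in Hz. If `NULL`, estimated as
#'   `1 / median(diff(t))`.
#' @return An object of class `tracker_series`: a list with fields `foot`,
#'   `t`, `pos`, `quat`, `rate_hz`.
#' @export
tracker_series <- function(foot, t, pos, quat, rate_hz = NULL) {
  foot <- match.arg(foot, c("left", "right"))
  t <- as.numeric(t)
  pos <- as.matrix(pos)
  quat <- as.matrix(quat)
  n <- length(t)
  if (nrow(pos) != n || nrow(quat) != n) {
    stop("tracker_series: t, pos and quat must have the same number of samples")
  }
  if (ncol(pos) != 3L) stop("tracker_series: pos must have 3 columns (x, y, z)")
  if (ncol(quat) != 4L) stop("tracker_series: quat must have 4 columns (qw, qx, qy, qz)")
  if (n >= 2L) {
    bad <- which(diff(t) <= 0)
    if (length(bad)) {
      stop(sprintf("tracker_series: timestamps not strictly increasing at index %d", bad[1] + 1L))
    }
  }
  if (n > 0L) {
    qn <- sqrt(rowSums(quat^2))
    bad <- which(abs(qn - 1) > 1e-6)
    if (length(bad)) {
      stop(sprintf("tracker_series: non-unit quaternion at index %d (norm %.8f)", bad[1], qn[bad[1]]))
    }
  }
  if (is.null(rate_hz)) {
    rate_hz <- if (n >= 2L) 1 / stats::median(diff(t)) else NA_real_
  }
  structure(
    list(foot = foot, t = t, pos = unname(pos), quat = unname(quat),
         rate_hz = rate_hz),
    class = "tracker_series"
  )
}

#' @export
print.tracker_series <- function(x, ...) {
  cat(sprintf("<tracker_series> foot=%s, %d samples, %.1f Hz, t in [%.3f, %.3f] s\n",
              x$foot, length(x$t), x$rate_hz,
              if (length(x$t)) min(x$t) else NA, if (length(x$t)) max(x$t) else NA))
  invisible(x)
}

#' @export
length.tracker_series <- function(x) length(x$t)

#' Read a tracker pose log (CSV)
#'
#' The log is a plain CSV with a mandatory header naming columns
#' `t, x, y, z, qw, qx, qy, qz`: time in seconds, world position in meters,
#' scalar-first unit quaternion. Extra columns are ignored.
#'
#' @param path Path to the CSV file.
#' @param foot `"left"` or `"right"` (the file format does not carry the side).
#' @return A [tracker_series] with `rate_hz` estimated from the median
#'   timestamp increment.
#' @export
read_tracker_log <- function(path, foot) {
  if (!file.exists(path)) stop(sprintf("tracker log not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("t", "x", "y", "z", "qw", "qx", "qy", "qz")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("tracker log %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  }
  tracker_series(
    foot = foot,
    t = df$t,
    pos = cbind(df$x, df$y, df$z),
    quat = cbind(df$qw, df$qx, df$qy, df$qz)
  )
}

#' Write a tracker pose log (CSV)
#'
#' @param series A [tracker_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracker_log <- function(series, path) {
  stopifnot(inherits(series, "tracker_series"))
  df <- data.frame(
    t = series$t,
    x = series$pos[, 1], y = series$pos[, 2], z = series$pos[, 3],
    qw = series$quat[, 1], qx = series$quat[, 2],
    qy = series$quat[, 3], qz = series$quat[, 4]
  )
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference gait-event table (CSV)
#'
#' The reference stream (typically exported from an instrumented walkway)
#' is a CSV with header `kind, foot, t`: event kind `HS` (heel strike) or
#' `TO` (toe off), foot side, time in seconds. Rows are validated and
#' sorted by `(foot, t)`. Within a foot, kinds are expected to alternate
#' HS/TO; violations are kept (real walkway exports can drop events) but
#' reported as a warning naming the offending line.
#'
#' @param path Path to the CSV file.
#' @param rate_hz Nominal sampling rate of the originating device in Hz
#'   (stored as an attribute; not used for parsing).
#' @return A `data.frame` with columns `kind`, `foot`, `t`, of class
#'   `gait_events`, with attribute `rate_hz`.
#' @export
read_reference_events <- function(path, rate_hz = NA_real_) {
  if (!file.exists(path)) stop(sprintf("reference event table not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = c(kind = "character", foot = "character"))
  need <- c("kind", "foot", "t")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("reference event table %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  }
  if (nrow(df)) {
    bad <- which(!df$kind %in% c("HS", "TO"))
    if (length(bad)) {
      stop(sprintf("reference event table %s: unknown event kind '%s' at line %d",
                   path, df$kind[bad[1]], bad[1] + 1L))
    }
    bad <- which(!df$foot %in% c("left", "right"))
    if (length(bad)) {
      stop(sprintf("reference event table %s: unknown foot '%s' at line %d",
                   path, df$foot[bad[1]], bad[1] + 1L))
    }
  }
  df <- df[order(df$foot, df$t), c("kind", "foot", "t"), drop = FALSE]
  rownames(df) <- NULL
  for (f in unique(df$foot)) {
    sub <- df[df$foot == f, ]
    if (nrow(sub) >= 2L) {
      if (any(diff(sub$t) <= 0)) {
        stop(sprintf("reference event table %s: duplicate/non-increasing times for %s foot", path, f))
      }
      rep_kind <- which(sub$kind[-1] == sub$kind[-nrow(sub)])
      if (length(rep_kind)) {
        warning(sprintf("reference events (%s foot): HS/TO alternation violated at t=%.4f s; rows kept",
                        f, sub$t[rep_kind[1] + 1L]))
      }
    }
  }
  structure(df, rate_hz = rate_hz, class = c("gait_events", "data.frame"))
}

#' Write a gait-event table (CSV)
#'
#' @param events Data frame with columns `kind`, `foot`, `t` (an `idx`
#'   column, if present, is written too).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  cols <- intersect(c("kind", "foot", "t", "idx"), names(events))
  df <- as.data.frame(events)[, cols, drop = FALSE]
  if (nrow(df)) {
    df$t <- format(df$t, digits = 17, scientific = FALSE, trim = TRUE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-stride feature table (CSV)
#'
#' One row per stride with columns `foot, t_hs_prev, t_to, t_hs_cur,
#' SL_m, ST_s, SW_m, SV_mps, STC_pct, SWC_pct, valid_SW`. Internal units
#' are SI (meters, seconds); presentation units (cm, ms, %) appear only in
#' validation reports.
#'
#' @param features Data frame as returned by [stride_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  cols <- c("foot", "t_hs_prev", "t_to", "t_hs_cur",
            "SL_m", "ST_s", "SW_m", "SV_mps", "STC_pct", "SWC_pct", "valid_SW")
  df <- as.data.frame(features)
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("write_features: missing column(s) %s", paste(miss, collapse = ", ")))
  }
  df <- df[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-stride feature table (CSV)
#'
#' @param path Path written by [write_features()].
#' @return Data frame with the standard feature columns.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop(sprintf("feature table not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = c(foot = "character"))
  df$valid_SW <- as.logical(df$valid_SW)
  df
}

#' Write / read a validation report (JSON)
#'
#' The report is serialized as JSON mirroring its in-memory structure:
#' per-event-kind sensitivity and offset statistics, and per-feature
#' agreement statistics (see [validation_report()]).
#'
#' @param report A `validation_report` list.
#' @param path Output path.
#' @return `path` invisibly (`write_report`); the report list
#'   (`read_report`).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop(sprintf("report not found: %s", path))
  rep <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  class(rep) <- "validation_report"
  rep
}

#' Run configuration
#'
#' Bundles the tunable parameters of the pipeline: filter specification,
#' event-matching tolerance, MAD outlier multiplier, heel offsets, optional
#' walkway bounding box and a known clock offset between the tracker and
#' reference streams.
#'
#' @param filter_order Butterworth order (default 3).
#' @param filter_cutoff_hz Low-pass cutoff in Hz (default 12).
#' @param match_tolerance_s Event-matching window in seconds. Default is
#'   [match_tolerance()]: 3 samples at 90 Hz = 33.3 ms.
#' @param outlier_k MAD multiplier for offset outlier rejection (default 3.5).
#' @param heel_offsets Named list: shoe-size label -> tracker-frame offset
#'   3-vector in meters (may be empty).
#' @param walkway_bbox `c(x_min, x_max, y_min, y_max)` in meters, or `NULL`
#'   to keep all cycles.
#' @param sync_offset_s Known clock offset in seconds added to reference
#'   event times relative to the tracker clock; it is subtracted from the
#'   reference stream before matching (default 0).
#' @param detector A [detector_params()] list.
#' @param seed Optional integer seed recorded in the config.
#' @return A list of class `run_config`.
#' @export
run_config <- function(filter_order = 3L,
                       filter_cutoff_hz = 12,
                       match_tolerance_s = match_tolerance(),
                       outlier_k = 3.5,
                       heel_offsets = list(),
                       walkway_bbox = NULL,
                       sync_offset_s = 0,
                       detector = detector_params(),
                       seed = NULL) {
  stopifnot(filter_order >= 1, filter_cutoff_hz > 0,
            match_tolerance_s > 0, outlier_k > 0)
  if (!is.null(walkway_bbox)) {
    stopifnot(length(walkway_bbox) == 4L,
              walkway_bbox[1] < walkway_bbox[2],
              walkway_bbox[3] < walkway_bbox[4])
  }
  structure(
    list(filter_order = as.integer(filter_order),
         filter_cutoff_hz = filter_cutoff_hz,
         match_tolerance_s = match_tolerance_s,
         outlier_k = outlier_k,
         heel_offsets = heel_offsets,
         walkway_bbox = walkway_bbox,
         sync_offset_s = sync_offset_s,
         detector = detector,
         seed = seed),
    class = "run_config"
  )
}

#' Default event-matching tolerance
#'
#' The matching window expressed as a whole number of sampling periods:
#' `n_samples / fs_hz` seconds. The default (3 samples at 90 Hz) is the
#' 33.3 ms window used to declare a detected event a true positive.
#'
#' @param n_samples Number of sampling periods (default 3).
#' @param fs_hz Sampling frequency in Hz (default 90).
#' @return Tolerance in seconds.
#' @export
match_tolerance <- function(n_samples = 3, fs_hz = 90) {
  stopifnot(n_samples > 0, fs_hz > 0)
  n_samples / fs_hz
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the arguments of [run_config()]; `filter` may be
#' a mapping with `order` and `cutoff_hz`; `heel_offsets` a mapping of
#' shoe-size label to `[ox, oy, oz]` meters; `detector` a mapping with
#' `min_prominence`, `min_peak_separation_s`, `min_cycle_s`, `max_cycle_s`.
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  det <- do.call(detector_params, if (is.null(y$detector)) list() else y$detector)
  run_config(
    filter_order = if (!is.null(y$filter$order)) y$filter$order else 3L,
    filter_cutoff_hz = if (!is.null(y$filter$cutoff_hz)) y$filter$cutoff_hz else 12,
    match_tolerance_s = if (!is.null(y$match_tolerance_s)) y$match_tolerance_s else match_tolerance(),
    outlier_k = if (!is.null(y$outlier_k)) y$outlier_k else 3.5,
    heel_offsets = if (!is.null(y$heel_offsets)) lapply(y$heel_offsets, as.numeric) else list(),
    walkway_bbox = if (!is.null(y$walkway_bbox)) as.numeric(y$walkway_bbox) else NULL,
    sync_offset_s = if (!is.null(y$sync_offset_s)) y$sync_offset_s else 0,
    detector = det,
    seed = y$seed
  )
}
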