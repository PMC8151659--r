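# Validation of detected events and features against a reference stream:
# tolerance-window one-to-one matching, sensitivity, MAD outlier rejection,
# offset statistics, RMSE, Pearson correlation, Bland-Altman limits of
# agreement.

#' Match detected events to reference events
#'
#' Greedy one-to-one matching in order of ascending absolute time
#' difference: the globally closest unmatched (detected, reference) pair
#' with `|dt| <= tol_s` is paired repeatedly until no admissible pair
#' remains. Unmatched reference events are false negatives; unmatched
#' detected events are false positives. Offsets are signed
#' `detected - reference`.
#'
#' @param detected,reference Numeric vectors of event times (one
#'   foot-and-kind stream each), seconds, time-ordered.
#' @param tol_s Matching tolerance in seconds (> 0); the default is 3
#'   samples at 90 Hz = 33.3 ms.
#' @return A list of class `match_result`: `matches` (data frame
#'   `det_idx`, `ref_idx`, `det_t`, `ref_t`, `offset_s`), and counts `TP`,
#'   `FN`, `FP`.
#' @export
match_events <- function(detected, reference, tol_s = match_tolerance()) {
  if (tol_s <= 0) stop("match_events: tol_s must be positive")
  detected <- as.numeric(detected)
  reference <- as.numeric(reference)
  nd <- length(detected)
  nr <- length(reference)
  pairs <- NULL
  if (nd && nr) {
    dt <- outer(detected, reference, `-`)
    cand <- which(abs(dt) <= tol_s, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(abs(dt[cand]), cand[, 2], cand[, 1])
      cand <- cand[ord, , drop = FALSE]
      used_d <- logical(nd)
      used_r <- logical(nr)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        di <- cand[i, 1]
        ri <- cand[i, 2]
        if (!used_d[di] && !used_r[ri]) {
          used_d[di] <- TRUE
          used_r[ri] <- TRUE
          keep[i] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand)) {
        ord <- order(cand[, 2])
        cand <- cand[ord, , drop = FALSE]
        pairs <- data.frame(det_idx = cand[, 1], ref_idx = cand[, 2],
                            det_t = detected[cand[, 1]],
                            ref_t = reference[cand[, 2]])
        pairs$offset_s <- pairs$det_t - pairs$ref_t
      }
    }
  }
  if (is.null(pairs)) {
    pairs <- data.frame(det_idx = integer(0), ref_idx = integer(0),
                        det_t = numeric(0), ref_t = numeric(0),
                        offset_s = numeric(0))
  }
  structure(list(matches = pairs,
                 TP = nrow(pairs),
                 FN = nr - nrow(pairs),
                 FP = nd - nrow(pairs)),
            class = "match_result")
}

#' Detection sensitivity
#'
#' Percentage of reference events recovered by the detector:
#' `100 * TP / (TP + FN)`. False positives are reported by
#' [match_events()] but do not enter the sensitivity.
#'
#' @param result A `match_result` from [match_events()], or a list with
#'   `TP` and `FN` counts.
#' @return Sensitivity in percent.
#' @export
sensitivity <- function(result) {
  if (result$TP + result$FN == 0) {
    stop("sensitivity: undefined, no reference events (TP + FN == 0)")
  }
  100 * result$TP / (result$TP + result$FN)
}

#' Robust outlier mask via the scaled median absolute deviation
#'
#' Flags values farther than `k` scaled MADs from the median, with
#' `scaled MAD = 1.4826 * median(|x - median(x)|)` (the normal-consistency
#' scaling, so the threshold is comparable to `k` standard deviations for
#' Gaussian data). When the MAD is zero (more than half the values
#' identical) every value different from the median is flagged. The mask is
#' invariant under affine rescaling of the data.
#'
#' @param values Numeric vector, length >= 3.
#' @param k Threshold multiplier (default 3.5).
#' @return Logical vector, `TRUE` where the value is an outlier.
#' @export
mad_outlier_mask <- function(values, k = 3.5) {
  if (length(values) < 3L) stop("mad_outlier_mask: need at least 3 values")
  if (k <= 0) stop("mad_outlier_mask: k must be positive")
  med <- stats::median(values)
  s <- stats::mad(values)          # 1.4826 * median(|x - med|)
  if (s == 0) values != med else abs(values - med) > k * s
}

#' Offset statistics
#'
#' Mean, standard deviation (n-1 denominator), mean and SD of absolute
#' values, and root-mean-square of the unmasked offsets. Units follow the
#' input (the report layer converts seconds to milliseconds).
#'
#' @param offsets Numeric vector of signed offsets.
#' @param mask Logical vector marking values to exclude (e.g. from
#'   [mad_outlier_mask()]); `NULL` keeps everything.
#' @return A list: `mean`, `sd`, `abs_mean`, `abs_sd`, `rmse`, `n`.
#' @export
offset_statistics <- function(offsets, mask = NULL) {
  x <- as.numeric(offsets)
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(x))
    x <- x[!mask]
  }
  if (!length(x)) stop("offset_statistics: no unmasked values")
  list(mean = mean(x),
       sd = if (length(x) > 1L) stats::sd(x) else 0,
       abs_mean = mean(abs(x)),
       abs_sd = if (length(x) > 1L) stats::sd(abs(x)) else 0,
       rmse = sqrt(mean(x^2)),
       n = length(x))
}

#' Bland-Altman limits of agreement
#'
#' The interval `mean(errors) +/- 1.96 * sd(errors)` within which ~95% of
#' between-method differences fall under normality (SD with n-1
#' denominator).
#'
#' @param errors Numeric vector of differences, length >= 2.
#' @return `c(lo, hi)`.
#' @export
limits_of_agreement <- function(errors) {
  if (length(errors) < 2L) stop("limits_of_agreement: need at least 2 values")
  m <- mean(errors)
  s <- stats::sd(errors)
  c(lo = m - 1.96 * s, hi = m + 1.96 * s)
}

#' Pair strides of two feature tables by their closing heel strikes
#'
#' Strides are identified by the matched HS events that close them:
#' per foot, the `t_hs_cur` streams of the two tables are matched with
#' [match_events()] at the given tolerance.
#'
#' @param vr_features,ref_features Feature tables (as from
#'   [stride_features()]).
#' @param tol_s Matching tolerance in seconds.
#' @return Data frame with columns `vr_row`, `ref_row` (row indices into
#'   the two tables).
#' @export
pair_strides <- function(vr_features, ref_features, tol_s = match_tolerance()) {
  out <- list()
  for (f in c("left", "right")) {
    vi <- which(vr_features$foot == f)
    ri <- which(ref_features$foot == f)
    if (!length(vi) || !length(ri)) next
    m <- match_events(vr_features$t_hs_cur[vi], ref_features$t_hs_cur[ri], tol_s)
    if (nrow(m$matches)) {
      out[[f]] <- data.frame(vr_row = vi[m$matches$det_idx],
                             ref_row = ri[m$matches$ref_idx])
    }
  }
  if (!length(out)) {
    return(data.frame(vr_row = integer(0), ref_row = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-feature agreement statistics
#'
#' For strides paired by their matched closing heel strikes, computes the
#' per-stride differences (VR minus reference) of SL, ST, SW, SV and STC%,
#' and summarizes each feature with mean offset and SD, mean absolute
#' error and SD, RMSE, Pearson correlation and limits of agreement.
#' Strides whose SW is invalid on either side are skipped for SW only.
#' When a feature has zero variance on either side, the correlation is
#' undefined and reported as `NA`.
#'
#' @param vr_features,ref_features Feature tables.
#' @param pairs Pairing from [pair_strides()].
#' @return Data frame, one row per feature, with columns `feature`, `n`,
#'   `mean_offset`, `sd_offset`, `mean_abs_error`, `sd_abs_error`, `rmse`,
#'   `pearson_r`, `loa_lo`, `loa_hi` (units of the underlying feature:
#'   m, s, m/s, %).
#' @export
feature_agreement <- function(vr_features, ref_features, pairs) {
  if (nrow(pairs) < 2L) {
    stop("feature_agreement: need at least 2 paired strides")
  }
  cols <- c(SL = "SL_m", ST = "ST_s", SW = "SW_m", SV = "SV_mps", STC = "STC_pct")
  rows <- list()
  for (feat in names(cols)) {
    col <- cols[[feat]]
    v <- vr_features[[col]][pairs$vr_row]
    r <- ref_features[[col]][pairs$ref_row]
    if (feat == "SW") {
      ok <- vr_features$valid_SW[pairs$vr_row] &
        ref_features$valid_SW[pairs$ref_row] & is.finite(v) & is.finite(r)
      v <- v[ok]
      r <- r[ok]
    }
    if (length(v) < 2L) {
      rows[[feat]] <- data.frame(feature = feat, n = length(v),
                                 mean_offset = NA_real_, sd_offset = NA_real_,
                                 mean_abs_error = NA_real_, sd_abs_error = NA_real_,
                                 rmse = NA_real_, pearson_r = NA_real_,
                                 loa_lo = NA_real_, loa_hi = NA_real_)
      next
    }
    d <- v - r
    st <- offset_statistics(d)
    loa <- limits_of_agreement(d)
    pr <- if (stats::sd(v) > 0 && stats::sd(r) > 0) stats::cor(v, r) else NA_real_
    rows[[feat]] <- data.frame(feature = feat, n = length(v),
                               mean_offset = st$mean, sd_offset = st$sd,
                               mean_abs_error = st$abs_mean,
                               sd_abs_error = st$abs_sd,
                               rmse = st$rmse, pearson_r = pr,
                               loa_lo = loa[["lo"]], loa_hi = loa[["hi"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a full validation report
#'
#' Matches detected events against the reference per (foot, kind) stream,
#' pools offsets per kind, removes MAD outliers from the offset series
#' before computing statistics, and (optionally) adds per-feature agreement
#' statistics from paired stride tables. Event statistics are reported in
#' milliseconds; feature statistics in presentation units (SL, SW in cm;
#' ST in ms; SV in cm/s; STC in %).
#'
#' @param detected Detected event data frame (columns `kind`, `foot`, `t`).
#' @param reference Reference event data frame (same columns). Reference
#'   times are shifted by `-config$sync_offset_s` onto the tracker clock
#'   before matching.
#' @param vr_features,ref_features Optional feature tables; when both are
#'   given, feature agreement is computed over strides paired at the
#'   matching tolerance.
#' @param config A [run_config()].
#' @return A list of class `validation_report` with elements `events`
#'   (per kind: sensitivity, counts, offset statistics, outliers, limits of
#'   agreement) and `features` (per feature: agreement statistics), plus
#'   `match_tolerance_ms`.
#' @export
validation_report <- function(detected, reference,
                              vr_features = NULL, ref_features = NULL,
                              config = run_config()) {
  ref <- as.data.frame(reference)
  ref$t <- ref$t - config$sync_offset_s
  det <- as.data.frame(detected)
  tol <- config$match_tolerance_s

  ev_out <- list()
  for (kind in c("HS", "TO")) {
    offsets <- numeric(0)
    TP <- 0L
    FN <- 0L
    FP <- 0L
    for (f in c("left", "right")) {
      d <- det$t[det$kind == kind & det$foot == f]
      r <- ref$t[ref$kind == kind & ref$foot == f]
      if (!length(d) && !length(r)) next
      m <- match_events(d, r, tol)
      offsets <- c(offsets, m$matches$offset_s)
      TP <- TP + m$TP
      FN <- FN + m$FN
      FP <- FP + m$FP
    }
    sens <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
    mask <- if (length(offsets) >= 3L) mad_outlier_mask(offsets, config$outlier_k)
            else rep(FALSE, length(offsets))
    kept <- offsets[!mask]
    st <- if (length(kept)) offset_statistics(kept) else NULL
    loa <- if (length(kept) >= 2L) limits_of_agreement(kept) * 1000 else c(lo = NA_real_, hi = NA_real_)
    ev_out[[kind]] <- list(
      cutoff_window_ms = tol * 1000,
      TP = TP, FN = FN, FP = FP,
      sensitivity_pct = sens,
      n_outliers = sum(mask),
      outlier_pct = if (length(offsets)) 100 * sum(mask) / length(offsets) else NA_real_,
      mean_offset_ms = if (!is.null(st)) st$mean * 1000 else NA_real_,
      sd_offset_ms = if (!is.null(st)) st$sd * 1000 else NA_real_,
      mean_abs_offset_ms = if (!is.null(st)) st$abs_mean * 1000 else NA_real_,
      sd_abs_offset_ms = if (!is.null(st)) st$abs_sd * 1000 else NA_real_,
      rmse_ms = if (!is.null(st)) st$rmse * 1000 else NA_real_,
      loa_ms = as.list(loa))
  }

  feat_out <- NULL
  if (!is.null(vr_features) && !is.null(ref_features)) {
    rf <- ref_features
    rf$t_hs_cur <- rf$t_hs_cur - config$sync_offset_s
    pairs <- pair_strides(vr_features, rf, tol)
    fa <- feature_agreement(vr_features, rf, pairs)
    # presentation units: SL, SW -> cm; ST -> ms; SV -> cm/s; STC -> %
    scale <- c(SL = 100, ST = 1000, SW = 100, SV = 100, STC = 1)
    unit <- c(SL = "cm", ST = "ms", SW = "cm", SV = "cm/s", STC = "%")
    feat_out <- list()
    for (i in seq_len(nrow(fa))) {
      feat <- fa$feature[i]
      s <- scale[[feat]]
      feat_out[[feat]] <- list(
        unit = unit[[feat]], n = fa$n[i],
        mean_offset = fa$mean_offset[i] * s,
        sd_offset = fa$sd_offset[i] * s,
        mean_abs_error = fa$mean_abs_error[i] * s,
        sd_abs_error = fa$sd_abs_error[i] * s,
        rmse = fa$rmse[i] * s,
        pearson_r = fa$pearson_r[i],
        loa = list(lo = fa$loa_lo[i] * s, hi = fa$loa_hi[i] * s))
    }
  }
  structure(list(match_tolerance_ms = tol * 1000,
                 events = ev_out, features = feat_out),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report (matching window %.1f ms)\n", x$match_tolerance_ms))
  for (kind in names(x$events)) {
    e <- x$events[[kind]]
    cat(sprintf("  %s: sensitivity %.1f%% (TP %d, FN %d, FP %d), mean offset %.1f +/- %.1f ms, mean |offset| %.1f +/- %.1f ms, outliers %d (%.1f%%)\n",
                kind, e$sensitivity_pct, e$TP, e$FN, e$FP,
                e$mean_offset_ms, e$sd_offset_ms,
                e$mean_abs_offset_ms, e$sd_abs_offset_ms,
                e$n_outliers, e$outlier_pct))
  }
  if (!is.null(x$features)) {
    for (feat in names(x$features)) {
      fe <- x$features[[feat]]
      cat(sprintf("  %-3s [%s]: mean offset %.2f +/- %.2f, MAE %.2f +/- %.2f, RMSE %.2f, r %.3f, LoA [%.2f, %.2f] (n=%d)\n",
                  feat, fe$unit, fe$mean_offset, fe$sd_offset,
                  fe$mean_abs_error, fe$sd_abs_error, fe$rmse,
                  fe$pearson_r, fe$loa$lo, fe$loa$hi, fe$n))
    }
  }
  invisible(x)
}
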