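# Rigid sensor-to-heel transformation. The tracker sits on the instep;
# gait features are defined at the heel, so every pose is mapped through a
# constant tracker-frame offset vector (measured per shoe size).

# Rotate row-vectors v (n x 3) by unit quaternions q (n x 4, scalar first):
# v' = v + 2*w*(u x v) + 2*(u x (u x v)), u = vector part.
quat_rotate <- function(quat, v) {
  q <- if (is.null(dim(quat))) matrix(quat, ncol = 4L) else as.matrix(quat)
  n <- nrow(q)
  V <- if (is.null(dim(v))) matrix(v, nrow = n, ncol = 3L, byrow = TRUE) else as.matrix(v)
  w <- q[, 1]
  u <- q[, 2:4, drop = FALSE]
  cross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  t1 <- 2 * cross(u, V)
  V + w * t1 + cross(u, t1)
}

#' Map tracker pose to heel position
#'
#' Computes `pos + R(quat) %*% offset`, where `R(quat)` is the rotation
#' matrix of the world-from-tracker unit quaternion and `offset` is the
#' heel position expressed in the tracker's local frame. Rotation preserves
#' length, so the heel is always exactly `|offset|` meters from the tracker.
#'
#' @param pos World tracker position: a 3-vector, or an `n x 3` matrix.
#' @param quat Scalar-first unit quaternion: a 4-vector, or an `n x 4`
#'   matrix. Quaternions off unit norm by more than `1e-6` are renormalized
#'   if within `1e-3` of unit, otherwise an error is raised.
#' @param offset Tracker-frame heel offset, meters (3-vector).
#' @return World heel position, same shape as `pos`.
#' @export
heel_position <- function(pos, quat, offset) {
  vec <- is.null(dim(pos))
  P <- if (vec) matrix(pos, ncol = 3L) else as.matrix(pos)
  Q <- if (is.null(dim(quat))) matrix(quat, ncol = 4L) else as.matrix(quat)
  stopifnot(nrow(P) == nrow(Q), length(offset) == 3L)
  qn <- sqrt(rowSums(Q^2))
  if (any(abs(qn - 1) > 1e-3)) {
    stop(sprintf("heel_position: quaternion norm %.6f too far from 1 at index %d",
                 qn[which(abs(qn - 1) > 1e-3)[1]], which(abs(qn - 1) > 1e-3)[1]))
  }
  if (any(abs(qn - 1) > 1e-6)) Q <- Q / qn
  out <- P + quat_rotate(Q, as.numeric(offset))
  if (vec) drop(out) else out
}

#' Apply the heel transformation to a whole tracker series
#'
#' @param series A [tracker_series].
#' @param offset Tracker-frame heel offset, meters (3-vector).
#' @return A [tracker_series] whose `pos` holds heel positions.
#' @export
heel_series <- function(series, offset) {
  stopifnot(inherits(series, "tracker_series"))
  out <- series
  if (length(series$t)) {
    out$pos <- heel_position(series$pos, series$quat, offset)
  }
  out
}

#' Look up the heel offset for a shoe size
#'
#' Exact-match lookup in a shoe-size table (no interpolation between
#' sizes). Offsets are tracker-frame 3-vectors in meters; each must be
#' finite with magnitude below 0.5 m.
#'
#' @param size_label Shoe-size label, e.g. `"EU42"`.
#' @param table Named list: size label -> offset 3-vector.
#' @return The offset 3-vector.
#' @export
offset_for_shoe_size <- function(size_label, table) {
  if (!length(table)) stop("offset_for_shoe_size: heel-offset table is empty")
  for (nm in names(table)) {
    v <- as.numeric(table[[nm]])
    if (length(v) != 3L || any(!is.finite(v)) || sqrt(sum(v^2)) >= 0.5) {
      stop(sprintf("offset_for_shoe_size: invalid offset for size '%s' (need finite 3-vector, |offset| < 0.5 m)", nm))
    }
  }
  if (!size_label %in% names(table)) {
    stop(sprintf("offset_for_shoe_size: unknown size '%s'; available: %s",
                 size_label, paste(names(table), collapse = ", ")))
  }
  as.numeric(table[[size_label]])
}

#' Read a heel-offset table from YAML
#'
#' The file maps shoe-size labels to `[ox, oy, oz]` offsets in meters,
#' expressed in the tracker's local frame. The package ships a placeholder
#' template (`system.file("extdata", "heel_offsets_template.yaml",
#' package = "vrgait")`); real offsets must be measured (e.g. with a
#' camera-based static capture) and supplied by the user.
#'
#' @param path Path to the YAML file.
#' @return Named list: size label -> offset 3-vector.
#' @export
read_heel_offsets <- function(path) {
  if (!file.exists(path)) stop(sprintf("heel-offset table not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y) || !length(y)) stop(sprintf("heel-offset table %s is empty", path))
  lapply(y, as.numeric)
}
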