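# Trajectory conditioning: zero-phase low-pass filtering, linear detrend,
# resampling. The tracker channels are filtered before any event logic; the
# vertical channel is additionally detrended so the stance floor sits near a
# constant baseline.

# Steady-state initial conditions for a direct-form-II-transposed IIR filter:
# the state vector that makes the step response start on its asymptote
# (solved from the companion form of the denominator).
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  if (a[1] != 1) {
    b <- b / a[1]
    a <- a / a[1]
  }
  comp <- rbind(-a[2:n], cbind(diag(n - 2L), rep(0, n - 2L)))
  IminusA <- diag(n - 1L) - t(comp)
  B <- b[2:n] - a[2:n] * b[1]
  solve(IminusA, B)
}

# One causal IIR pass over the columns of X (direct form II transposed),
# Zi = per-unit steady state scaled by the caller.
iir_filter_cols <- function(b, a, X, Zi) {
  n <- nrow(X)
  m <- length(b) - 1L
  Y <- matrix(0, n, ncol(X))
  Z <- Zi
  for (i in seq_len(n)) {
    xi <- X[i, ]
    yi <- b[1] * xi + Z[1, ]
    if (m > 1L) {
      for (k in seq_len(m - 1L)) {
        Z[k, ] <- b[k + 1L] * xi + Z[k + 1L, ] - a[k + 1L] * yi
      }
    }
    Z[m, ] <- b[m + 1L] * xi - a[m + 1L] * yi
    Y[i, ] <- yi
  }
  Y
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies an order-`order` low-pass Butterworth filter forward and backward
#' (zero phase shift; effective magnitude response is the squared single-pass
#' response, so the gain at the cutoff frequency is exactly 1/2). Edges are
#' handled by odd-reflection padding of `3 * (order + 1)` samples with
#' steady-state initial conditions, so a constant signal passes through
#' unchanged to machine precision.
#'
#' @param x Numeric vector, or matrix with one channel per column.
#' @param fs Sampling frequency in Hz.
#' @param cutoff_hz Low-pass cutoff in Hz; must be below the Nyquist
#'   frequency `fs / 2`.
#' @param order Filter order (default 3).
#' @return Filtered signal, same shape as `x`.
#' @export
lowpass_zero_phase <- function(x, fs, cutoff_hz = 12, order = 3L) {
  stopifnot(fs > 0, order >= 1)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop(sprintf("lowpass_zero_phase: cutoff %.3f Hz must lie in (0, Nyquist = %.3f Hz)",
                 cutoff_hz, fs / 2))
  }
  vec <- is.null(dim(x))
  X <- if (vec) matrix(as.numeric(x), ncol = 1L) else as.matrix(x)
  pad <- 3L * (as.integer(order) + 1L)
  n <- nrow(X)
  if (n <= pad) {
    stop(sprintf("lowpass_zero_phase: signal length %d too short; need more than %d samples for order %d",
                 n, pad, order))
  }
  ba <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  b <- ba$b
  a <- ba$a
  zi <- lfilter_zi(b, a)

  # odd reflection about the first/last samples
  front <- 2 * X[rep(1L, pad), , drop = FALSE] - X[(pad + 1L):2L, , drop = FALSE]
  back <- 2 * X[rep(n, pad), , drop = FALSE] - X[(n - 1L):(n - pad), , drop = FALSE]
  Xp <- rbind(front, X, back)

  Zi <- outer(zi, Xp[1L, ])
  Y <- iir_filter_cols(b, a, Xp, Zi)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Zi <- outer(zi, Y[1L, ])
  Y <- iir_filter_cols(b, a, Y, Zi)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y <- Y[(pad + 1L):(pad + n), , drop = FALSE]
  if (vec) drop(Y) else Y
}

#' Remove the least-squares straight line from a signal
#'
#' Subtracts the best-fit (least squares) linear trend. The residual has
#' zero mean and zero best-fit slope, and the operation is idempotent.
#'
#' @param x Numeric vector of at least 2 samples.
#' @return Detrended vector, same length.
#' @export
detrend_linear <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("detrend_linear: need at least 2 samples")
  i <- seq_len(n) - (n + 1) / 2          # centred index: orthogonal to intercept
  slope <- sum(i * x) / sum(i * i)
  x - mean(x) - slope * i
}

#' Resample a tracker series onto a uniform grid
#'
#' Linearly interpolates position (and quaternion components, renormalized
#' afterwards) onto a uniform `fs_target` grid spanning the original time
#' range. Used e.g. to bring a 120 Hz stream to the 90 Hz analysis rate.
#'
#' @param series A [tracker_series].
#' @param fs_target Target sampling frequency in Hz.
#' @return A [tracker_series] at `fs_target`.
#' @export
resample_tracker <- function(series, fs_target) {
  stopifnot(inherits(series, "tracker_series"), fs_target > 0)
  n <- length(series$t)
  if (n == 0L) {
    return(tracker_series(series$foot, numeric(0),
                          matrix(0, 0, 3), matrix(0, 0, 4), rate_hz = fs_target))
  }
  t0 <- series$t[1]
  t1 <- series$t[n]
  tg <- t0 + seq(0, floor((t1 - t0) * fs_target)) / fs_target
  interp <- function(y) stats::approx(series$t, y, xout = tg)$y
  pos <- vapply(1:3, function(j) interp(series$pos[, j]), numeric(length(tg)))
  quat <- vapply(1:4, function(j) interp(series$quat[, j]), numeric(length(tg)))
  pos <- matrix(pos, ncol = 3L)
  quat <- matrix(quat, ncol = 4L)
  quat <- quat / sqrt(rowSums(quat^2))
  tracker_series(series$foot, tg, pos, quat, rate_hz = fs_target)
}

#' Snap event times to a uniform sampling grid
#'
#' Each time is replaced by the nearest instant of the grid
#' `{k / fs : k integer}` anchored at `t0` (default 0). This is how
#' reference event streams recorded at a different rate are aligned to the
#' tracker analysis rate: events, not waveforms, are what the reference
#' device contributes.
#'
#' @param t Numeric vector of event times in seconds.
#' @param fs Grid frequency in Hz.
#' @param t0 Grid anchor in seconds (default 0).
#' @return Snapped times, same length.
#' @export
snap_event_times <- function(t, fs, t0 = 0) {
  stopifnot(fs > 0)
  t0 + round((t - t0) * fs) / fs
}

#' Resample a reference event table to a grid
#'
#' Convenience wrapper: applies [snap_event_times()] to the `t` column.
#'
#' @param events A gait-event data frame (columns `kind`, `foot`, `t`).
#' @param fs_target Target grid frequency in Hz.
#' @param t0 Grid anchor (default 0).
#' @return The table with snapped times.
#' @export
resample_events <- function(events, fs_target, t0 = 0) {
  events$t <- snap_event_times(events$t, fs_target, t0)
  events
}
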