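#' Construct an eye-position trace
#'
#' An `eye_trace` holds a uniformly sampled binocular-average gaze signal.
#' The unit tag distinguishes raw tracker output (`"volts"`) from calibrated
#' screen coordinates (`"degrees"`) and propagates through every transform so
#' that kinematic quantities are only ever computed on calibrated data.
#'
#' @param t Numeric vector of timestamps in milliseconds, strictly increasing
#'   with a uniform step.
#' @param x,y Numeric vectors of horizontal and vertical gaze position, same
#'   length as `t`, in `unit`.
#' @param unit `"volts"` (raw tracker) or `"degrees"` (calibrated).
#' @param rate_hz Nominal sampling rate in Hz (typically 120 for a video
#'   tracker or 1000 when digitized with the neural signal). Defaults to the
#'   rate implied by the median timestamp step.
#'
#' @return An object of class `eye_trace`: a list with elements `t`, `x`,
#'   `y`, `unit`, `rate_hz`.
#' @examples
#' tr <- eye_trace(t = seq(0, 999), x = rnorm(1000), y = rnorm(1000),
#'                 unit = "degrees")
#' tr$rate_hz
#' @export
eye_trace <- function(t, x, y, unit = c("volts", "degrees"), rate_hz = NULL) {
  unit <- match.arg(unit)
  if (length(t) == 0L) fv_input_error("empty trace")
  if (length(t) != length(x) || length(t) != length(y))
    fv_input_error("t, x, y must have equal length")
  if (anyNA(t) || is.unsorted(t, strictly = TRUE))
    fv_input_error("timestamps must be strictly increasing")
  step <- if (length(t) > 1L) median(diff(t)) else NA_real_
  if (is.null(rate_hz)) {
    if (is.na(step)) fv_input_error("rate_hz required for single-sample trace")
    rate_hz <- 1000 / step
  }
  if (!is.na(step)) {
    dts <- diff(t)
    if (any(abs(dts - 1000 / rate_hz) > 0.01 * (1000 / rate_hz)))
      fv_input_error("trace is not uniformly sampled at rate_hz (within 1%)")
  }
  structure(
    list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         unit = unit, rate_hz = rate_hz),
    class = "eye_trace"
  )
}

#' @export
print.eye_trace <- function(x, ...) {
  cat(sprintf("<eye_trace> %d samples @ %g Hz, unit = %s, span %.1f-%.1f ms\n",
              length(x$t), x$rate_hz, x$unit, x$t[1], x$t[length(x$t)]))
  invisible(x)
}

#' @export
length.eye_trace <- function(x) length(x$t)

#' Centered moving-average smoothing
#'
#' Smooths the x and y channels with a centered moving average. The window
#' length in samples is the odd count nearest to
#' `window_ms * rate_hz / 1000` (minimum 1), so a 20 ms window is 21 samples
#' at 1 kHz and 3 samples at 120 Hz. At the edges the window shrinks to the
#' available samples, so the output has the same length as the input and
#' event-aligned indexing is preserved.
#'
#' @param trace An [eye_trace()].
#' @param window_ms Window length in milliseconds (default 20).
#' @return A smoothed `eye_trace` with the same unit and rate.
#' @export
moving_average <- function(trace, window_ms = 20) {
  stopifnot(inherits(trace, "eye_trace"))
  if (length(trace$t) == 0L) fv_input_error("empty trace")
  if (window_ms <= 0) fv_input_error("window_ms must be positive")
  w <- ma_window_samples(window_ms, trace$rate_hz)
  trace$x <- ma_shrink(trace$x, w)
  trace$y <- ma_shrink(trace$y, w)
  trace
}

# odd sample count nearest to window_ms * rate_hz / 1000, at least 1
ma_window_samples <- function(window_ms, rate_hz) {
  k <- window_ms * rate_hz / 1000
  max(1L, 2L * as.integer(round((k - 1) / 2)) + 1L)
}

# centered moving average with shrinking (truncated) edge windows, O(n)
ma_shrink <- function(v, w) {
  if (w <= 1L) return(v)
  n <- length(v)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Gaze kinematics: velocity, speed, acceleration
#'
#' Component velocities are computed by central differences (one-sided at the
#' trace ends) on a calibrated trace; angular speed is the Euclidean norm of
#' the velocity components, and angular acceleration is the central
#' difference of the speed. Central differencing is unbiased to second order
#' on a uniform grid.
#'
#' @param trace An [eye_trace()] in degrees with at least 3 samples
#'   (typically smoothed first with [moving_average()]).
#' @return A `kin_trace`: list with `t` (ms), `vx`, `vy`, `speed` (deg/s),
#'   and `accel` (deg/s^2), all the same length as the trace.
#' @export
kinematics <- function(trace) {
  stopifnot(inherits(trace, "eye_trace"))
  if (trace$unit != "degrees") fv_input_error("calibrate first")
  n <- length(trace$t)
  if (n < 3L) fv_input_error("need at least 3 samples")
  dt_s <- 1 / trace$rate_hz
  vx <- central_diff(trace$x, dt_s)
  vy <- central_diff(trace$y, dt_s)
  speed <- sqrt(vx^2 + vy^2)
  accel <- central_diff(speed, dt_s)
  structure(list(t = trace$t, vx = vx, vy = vy, speed = speed, accel = accel),
            class = "kin_trace")
}

central_diff <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

#' Dispersion-based fixation detection
#'
#' Detects fixations with a dispersion criterion in the style of the I-DT
#' algorithm: a maximal run of samples qualifies as a fixation when the range
#' (max minus min) of x and of y both stay within `dispersion_thresh` and the
#' run lasts at least `min_duration_ms`. The trace is expected to be smoothed
#' by the caller (the pipeline applies [moving_average()] first). Works in
#' the trace's own unit, so the threshold is in volts for a raw trace and in
#' degrees for a calibrated one.
#'
#' The scan is greedy left-to-right with running window extrema, so returned
#' fixations are time-ordered and disjoint, and each is maximal given the
#' preceding detections.
#'
#' @param trace An [eye_trace()] (any unit).
#' @param min_duration_ms Minimum fixation duration in ms (default 500,
#'   which also excludes incidental short fixations from calibration).
#' @param dispersion_thresh Maximum allowed per-axis range over the
#'   fixation, in the trace's unit.
#' @return A data frame with one row per fixation: `t_start`, `t_end`,
#'   `duration` (ms), `cx`, `cy` (mean position over the fixation, trace
#'   unit), `label` (NA until assigned by [label_fixations()]).
#' @export
detect_fixations <- function(trace, min_duration_ms = 500, dispersion_thresh) {
  stopifnot(inherits(trace, "eye_trace"))
  if (missing(dispersion_thresh) || is.null(dispersion_thresh))
    fv_input_error("dispersion_thresh is required (trace units)")
  if (min_duration_ms <= 0 || dispersion_thresh <= 0)
    fv_input_error("thresholds must be positive")
  tt <- trace$t; x <- trace$x; y <- trace$y
  n <- length(tt)
  # monotonic deques of indices for running max/min of x and y over [s, j]
  qxM <- integer(n); qxm <- integer(n); qyM <- integer(n); qym <- integer(n)
  hxM <- 1L; txM <- 0L; hxm <- 1L; txm <- 0L
  hyM <- 1L; tyM <- 0L; hym <- 1L; tym <- 0L
  starts <- integer(0); ends <- integer(0)
  s <- 1L
  j <- 0L
  while (j < n) {
    j <- j + 1L
    xv <- x[j]; yv <- y[j]
    while (txM >= hxM && x[qxM[txM]] <= xv) txM <- txM - 1L
    txM <- txM + 1L; qxM[txM] <- j
    while (txm >= hxm && x[qxm[txm]] >= xv) txm <- txm - 1L
    txm <- txm + 1L; qxm[txm] <- j
    while (tyM >= hyM && y[qyM[tyM]] <= yv) tyM <- tyM - 1L
    tyM <- tyM + 1L; qyM[tyM] <- j
    while (tym >= hym && y[qym[tym]] >= yv) tym <- tym - 1L
    tym <- tym + 1L; qym[tym] <- j
    while (x[qxM[hxM]] - x[qxm[hxm]] > dispersion_thresh ||
           y[qyM[hyM]] - y[qym[hym]] > dispersion_thresh) {
      # adding j broke the dispersion bound for [s, j]
      if (j - 1L > s && tt[j - 1L] - tt[s] >= min_duration_ms) {
        starts <- c(starts, s); ends <- c(ends, j - 1L)
        s <- j
      } else {
        s <- s + 1L
      }
      while (hxM <= txM && qxM[hxM] < s) hxM <- hxM + 1L
      while (hxm <= txm && qxm[hxm] < s) hxm <- hxm + 1L
      while (hyM <= tyM && qyM[hyM] < s) hyM <- hyM + 1L
      while (hym <= tym && qym[hym] < s) hym <- hym + 1L
    }
  }
  if (n > s && tt[n] - tt[s] >= min_duration_ms) {
    starts <- c(starts, s); ends <- c(ends, n)
  }
  data.frame(
    t_start = tt[starts],
    t_end = tt[ends],
    duration = tt[ends] - tt[starts],
    cx = vapply(seq_along(starts),
                function(k) mean(x[starts[k]:ends[k]]), numeric(1)),
    cy = vapply(seq_along(starts),
                function(k) mean(y[starts[k]:ends[k]]), numeric(1)),
    label = rep(NA_integer_, length(starts))
  )
}
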