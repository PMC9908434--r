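#' Calibration stimulus schedule
#'
#' Describes when and where the salient flickering calibration stimuli were
#' shown. The default protocol shows a 1 degree spot flickering at 30 Hz for
#' 2 minutes at each of five screen locations: center, and 7 degrees right,
#' up, left, and down.
#'
#' @param locations Two-column matrix (or data frame) of stimulus screen
#'   locations in degrees, one row per epoch.
#' @param epoch_s Duration of each epoch in seconds (default 120).
#' @param t0_ms Session time at which the first epoch starts.
#' @param stimulus_deg Stimulus diameter in degrees (display property).
#' @param flicker_hz Flicker rate in Hz (display property).
#' @return A `calibration_schedule`: data frame with `epoch`, `x_deg`,
#'   `y_deg`, `t_start_ms`, `t_end_ms` plus attributes `stimulus_deg`,
#'   `flicker_hz`.
#' @export
calibration_schedule <- function(locations = default_calibration_locations(),
                                 epoch_s = 120, t0_ms = 0,
                                 stimulus_deg = 1, flicker_hz = 30) {
  locations <- as.matrix(locations)
  if (ncol(locations) != 2L || nrow(locations) < 1L)
    fv_input_error("locations must be an n x 2 matrix of degrees")
  n <- nrow(locations)
  sched <- data.frame(
    epoch = seq_len(n),
    x_deg = as.numeric(locations[, 1]),
    y_deg = as.numeric(locations[, 2]),
    t_start_ms = t0_ms + (seq_len(n) - 1) * epoch_s * 1000,
    t_end_ms = t0_ms + seq_len(n) * epoch_s * 1000
  )
  attr(sched, "stimulus_deg") <- stimulus_deg
  attr(sched, "flicker_hz") <- flicker_hz
  class(sched) <- c("calibration_schedule", "data.frame")
  sched
}

#' @rdname calibration_schedule
#' @export
default_calibration_locations <- function() {
  matrix(c(0, 0, 7, 0, 0, 7, -7, 0, 0, -7), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("x_deg", "y_deg")))
}

#' Assign fixations to calibration epochs
#'
#' A fixation is labeled with an epoch index only when its full
#' `[t_start, t_end]` interval lies inside that epoch; fixations straddling
#' epoch boundaries (or outside the schedule) stay unassigned (`NA`).
#'
#' @param fixations Data frame from [detect_fixations()].
#' @param schedule A [calibration_schedule()].
#' @return The fixation data frame with the `label` column filled in.
#' @export
label_fixations <- function(fixations, schedule) {
  if (nrow(schedule) == 0L) fv_input_error("empty schedule")
  lab <- rep(NA_integer_, nrow(fixations))
  for (i in seq_len(nrow(schedule))) {
    inside <- fixations$t_start >= schedule$t_start_ms[i] &
      fixations$t_end <= schedule$t_end_ms[i]
    lab[inside] <- schedule$epoch[i]
  }
  fixations$label <- lab
  fixations
}

#' Gaussian fit to a fixation-coordinate histogram
#'
#' Fits the amplitude-parameterized Gaussian a * exp(-((x - b) / c)^2) to a
#' histogram of the values by nonlinear least squares. `b` is the cluster
#' center and `c` the width parameter; the Gaussian standard deviation is
#' `c / sqrt(2)`. Histogram bin width follows the Freedman-Diaconis rule
#' with a floor of 8 bins. Initial guesses are `a` = tallest bin, `b` =
#' sample mean, `c` = sample SD * sqrt(2). If the optimizer fails, the fit
#' falls back to robust moments (`b` = median, `c` = 1.4826 * MAD * sqrt(2))
#' with `rmse = NaN` and `fallback = TRUE`.
#'
#' @param values Numeric vector of per-fixation coordinates (one axis), in
#'   source units.
#' @param min_fixations Minimum number of values required (default 5).
#' @return A `gaussian_fit`: list with `a`, `b`, `c`, `rmse`, `fallback`.
#' @export
fit_gaussian <- function(values, min_fixations = 5) {
  values <- values[is.finite(values)]
  if (length(values) < min_fixations)
    fv_input_error("insufficient fixations for cluster")
  hg <- cluster_histogram(values)
  a0 <- max(hg$counts)
  b0 <- mean(values)
  c0 <- sd(values) * sqrt(2)
  if (!is.finite(c0) || c0 <= 0) c0 <- max(diff(range(values)) / 4, 1e-6)
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      counts ~ a * exp(-((mids - b) / c)^2),
      data = hg,
      start = list(a = a0, b = b0, c = c0),
      lower = c(a = 0, b = min(values), c = 1e-12),
      upper = c(a = Inf, b = max(values), c = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    p <- coef(m)
    list(a = unname(p["a"]), b = unname(p["b"]), c = abs(unname(p["c"])),
         rmse = sqrt(mean(resid(m)^2)), fallback = FALSE)
  }, error = function(e) NULL)
  # a width parameter wider than the whole data span means the optimizer
  # settled on a flat line, not a cluster (a true Gaussian sample has
  # c ~ 0.25 * span); fall back to robust moments, scoring their curve
  # against the histogram so a poor fit still reports a numeric rmse
  if (!is.null(fit) && fit$c > diff(range(values)) &&
      diff(range(values)) > 0) {
    b_r <- median(values)
    c_r <- max(mad(values) * sqrt(2), 1e-6)
    fit <- list(a = a0, b = b_r, c = c_r,
                rmse = sqrt(mean((hg$counts -
                                    a0 * exp(-((hg$mids - b_r) / c_r)^2))^2)),
                fallback = TRUE)
  }
  if (is.null(fit)) {
    fit <- list(a = a0, b = median(values),
                c = max(mad(values) * sqrt(2), 1e-6),
                rmse = NaN, fallback = TRUE)
  }
  structure(fit, class = "gaussian_fit")
}

# Freedman-Diaconis histogram with a floor of 8 bins; the grid is extended
# by half a bin on each side so the extreme values sit at bin centers,
# which keeps the histogram of a symmetric sample symmetric
cluster_histogram <- function(values) {
  rng <- range(values)
  span <- diff(rng)
  if (span == 0) {
    rng <- rng + c(-0.5, 0.5)
    span <- 1
  }
  h <- 2 * stats::IQR(values) / length(values)^(1 / 3)
  nbins <- if (h > 0) max(8L, ceiling(span / h)) else 8L
  bw <- span / nbins
  breaks <- seq(rng[1] - bw / 2, rng[2] + bw / 2, length.out = nbins + 2)
  hh <- graphics::hist(values, breaks = breaks, plot = FALSE,
                       include.lowest = TRUE)
  data.frame(mids = hh$mids, counts = hh$counts)
}

#' Estimate per-axis gain and offset from labeled fixations
#'
#' For every epoch with at least `min_fixations` labeled fixations, the x
#' and y fixation coordinates are each fitted with [fit_gaussian()], giving
#' a raw-unit cluster center (b_x, b_y). The Gaussian centers are then
#' regressed, per axis, against the known stimulus locations in degrees by
#' ordinary least squares across epochs; the slope is the gain (degrees per
#' source unit) and the intercept the offset, i.e. deg = gain * raw +
#' offset. Using the regression line pools all epochs instead of a
#' two-point solution. Cluster widths are mapped to degrees through the
#' estimated gain, and residuals are the distances between the calibrated
#' cluster centers and the stimulus locations.
#'
#' @param labeled Fixations labeled by [label_fixations()], with centroids
#'   in raw source units.
#' @param schedule The [calibration_schedule()] used.
#' @param min_fixations Minimum fixations per epoch for a cluster fit
#'   (default 5).
#' @return A `calibration_result`: list with `cal_x`, `cal_y` (each
#'   `gain`/`offset`), `centers` (per-epoch data frame of raw and
#'   calibrated cluster centers, widths, fixation counts, residual
#'   distance), `cluster_sd_deg` (per-epoch per-axis SDs in degrees),
#'   `pooled_sd_deg`, `n_epochs_used`.
#' @export
estimate_calibration <- function(labeled, schedule, min_fixations = 5) {
  if (nrow(schedule) == 0L) fv_input_error("empty schedule")
  eps <- schedule$epoch
  centers <- data.frame(
    epoch = eps, x_deg = schedule$x_deg, y_deg = schedule$y_deg,
    n_fix = 0L, bx_raw = NA_real_, by_raw = NA_real_,
    cx_width = NA_real_, cy_width = NA_real_
  )
  for (i in seq_along(eps)) {
    vals <- labeled[!is.na(labeled$label) & labeled$label == eps[i], ,
                    drop = FALSE]
    centers$n_fix[i] <- nrow(vals)
    if (nrow(vals) >= min_fixations) {
      fx <- fit_gaussian(vals$cx, min_fixations)
      fy <- fit_gaussian(vals$cy, min_fixations)
      centers$bx_raw[i] <- fx$b
      centers$by_raw[i] <- fy$b
      centers$cx_width[i] <- fx$c
      centers$cy_width[i] <- fy$c
    }
  }
  ok <- !is.na(centers$bx_raw) & !is.na(centers$by_raw)
  if (length(unique(centers$x_deg[ok])) < 2L ||
      length(unique(centers$y_deg[ok])) < 2L)
    fv_input_error("degenerate schedule")
  fit_x <- lm(x_deg ~ bx_raw, data = centers[ok, ])
  fit_y <- lm(y_deg ~ by_raw, data = centers[ok, ])
  cal_x <- list(gain = unname(coef(fit_x)[2]),
                offset = unname(coef(fit_x)[1]), axis = "X")
  cal_y <- list(gain = unname(coef(fit_y)[2]),
                offset = unname(coef(fit_y)[1]), axis = "Y")
  centers$bx_cal <- cal_x$gain * centers$bx_raw + cal_x$offset
  centers$by_cal <- cal_y$gain * centers$by_raw + cal_y$offset
  centers$sd_x_deg <- abs(cal_x$gain) * centers$cx_width / sqrt(2)
  centers$sd_y_deg <- abs(cal_y$gain) * centers$cy_width / sqrt(2)
  centers$residual_deg <- sqrt((centers$bx_cal - centers$x_deg)^2 +
                                 (centers$by_cal - centers$y_deg)^2)
  pooled <- sqrt(mean(c(centers$sd_x_deg[ok]^2, centers$sd_y_deg[ok]^2)))
  structure(
    list(cal_x = cal_x, cal_y = cal_y, centers = centers,
         pooled_sd_deg = pooled, n_epochs_used = sum(ok),
         min_fixations = min_fixations),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> gain (%.4g, %.4g) deg/unit, offset (%.4g, %.4g) deg\n",
    x$cal_x$gain, x$cal_y$gain, x$cal_x$offset, x$cal_y$offset))
  cat(sprintf("  %d/%d epochs used, pooled cluster SD %.3g deg\n",
              x$n_epochs_used, nrow(x$centers), x$pooled_sd_deg))
  invisible(x)
}

#' Apply (or invert) a calibration on a trace
#'
#' `apply_calibration` maps a raw trace to degrees with
#' deg = gain * raw + offset per axis; `invert_calibration` is the exact
#' affine inverse, mapping degrees back to raw units.
#'
#' @param trace An [eye_trace()] in volts (`apply_calibration`) or degrees
#'   (`invert_calibration`).
#' @param result A [estimate_calibration()] result (or any list with
#'   `cal_x`/`cal_y` gain and offset).
#' @return The transformed `eye_trace` with the unit tag flipped.
#' @export
apply_calibration <- function(trace, result) {
  stopifnot(inherits(trace, "eye_trace"))
  if (trace$unit != "volts")
    fv_input_error("trace is already calibrated (unit degrees)")
  trace$x <- result$cal_x$gain * trace$x + result$cal_x$offset
  trace$y <- result$cal_y$gain * trace$y + result$cal_y$offset
  trace$unit <- "degrees"
  trace
}

#' @rdname apply_calibration
#' @export
invert_calibration <- function(trace, result) {
  stopifnot(inherits(trace, "eye_trace"))
  if (trace$unit != "degrees")
    fv_input_error("trace is not in degrees")
  trace$x <- (trace$x - result$cal_x$offset) / result$cal_x$gain
  trace$y <- (trace$y - result$cal_y$offset) / result$cal_y$gain
  trace$unit <- "volts"
  trace
}

#' Offset-only recalibration from fixation-point fixations
#'
#' In later sessions the gains are kept and only the offsets are touched up
#' from the displacement between fixations on a known fixation point and
#' that point's screen location.
#'
#' @param fixations_on_fp Fixations (in degrees) recorded while the subject
#'   fixated the fixation point.
#' @param fp_location Length-2 numeric, fixation-point location in degrees.
#' @param result A `calibration_result` to adjust.
#' @param min_fixations Minimum number of fixations required (default 5).
#' @return The adjusted `calibration_result` (gains unchanged).
#' @export
offset_recalibrate <- function(fixations_on_fp, fp_location, result,
                               min_fixations = 5) {
  if (is.null(fixations_on_fp) || nrow(fixations_on_fp) == 0L)
    fv_input_error("no fixations on the fixation point")
  if (nrow(fixations_on_fp) < min_fixations)
    fv_input_error("insufficient fixations for cluster")
  dx <- fp_location[1] - mean(fixations_on_fp$cx)
  dy <- fp_location[2] - mean(fixations_on_fp$cy)
  result$cal_x$offset <- result$cal_x$offset + dx
  result$cal_y$offset <- result$cal_y$offset + dy
  result
}

#' Calibration residual summary
#'
#' Summarizes how well the calibrated cluster centers land on the true
#' stimulus locations: per-axis mean offset and SD across epochs, and the
#' per-epoch residual distances. Epochs without enough fixations appear
#' with `NA` rather than zero.
#'
#' @param result A [estimate_calibration()] result.
#' @return A list with `summary` (per-axis mean offset and SD, mean residual
#'   distance, in degrees) and `per_epoch` (epoch, stimulus location,
#'   calibrated center, residual distance), both plain data frames ready for
#'   CSV serialization.
#' @export
residual_report <- function(result) {
  ce <- result$centers
  off_x <- ce$bx_cal - ce$x_deg
  off_y <- ce$by_cal - ce$y_deg
  list(
    summary = data.frame(
      axis = c("X", "Y"),
      mean_offset_deg = c(mean(off_x, na.rm = TRUE), mean(off_y, na.rm = TRUE)),
      sd_offset_deg = c(sd(off_x[!is.na(off_x)]), sd(off_y[!is.na(off_y)])),
      mean_residual_deg = rep(mean(ce$residual_deg, na.rm = TRUE), 2)
    ),
    per_epoch = data.frame(
      epoch = ce$epoch, x_deg = ce$x_deg, y_deg = ce$y_deg,
      bx_cal = ce$bx_cal, by_cal = ce$by_cal, n_fix = ce$n_fix,
      residual_deg = ce$residual_deg,
      absent = is.na(ce$bx_raw)
    )
  )
}

#' End-to-end calibration of a raw trace
#'
#' Convenience pipeline: smooth the raw trace, detect fixations longer than
#' `min_fix_ms`, label them by calibration epoch, and estimate the per-axis
#' gain and offset.
#'
#' @param trace_volts Raw [eye_trace()] in volts.
#' @param schedule A [calibration_schedule()].
#' @param dispersion_thresh Fixation dispersion bound in volts (for a
#'   tracker with a nominal scale around 5 deg/V, 0.3 V corresponds to the
#'   1.5 degree default used on calibrated data).
#' @param min_fix_ms Minimum fixation duration in ms (default 500).
#' @param window_ms Smoothing window in ms (default 20).
#' @param min_fixations Minimum fixations per cluster (default 5).
#' @return A `calibration_result`.
#' @export
calibrate_trace <- function(trace_volts, schedule, dispersion_thresh = 0.3,
                            min_fix_ms = 500, window_ms = 20,
                            min_fixations = 5) {
  sm <- moving_average(trace_volts, window_ms)
  fx <- detect_fixations(sm, min_duration_ms = min_fix_ms,
                         dispersion_thresh = dispersion_thresh)
  lab <- label_fixations(fx, schedule)
  estimate_calibration(lab, schedule, min_fixations = min_fixations)
}
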