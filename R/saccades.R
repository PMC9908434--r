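#' Polar amplitude-direction binning for saccades
#'
#' The motor-field analysis categorizes saccades into six direction bins of
#' 60 degrees each (0 = rightward, counterclockwise positive) and three
#' amplitude bands: short (< 5 degrees), medium (5-10 degrees), and long
#' (> 10 degrees). Bins are half-open, `[0, 5)`, `[5, 10)`, `[10, Inf)`, so
#' every saccade falls in exactly one bin; the direction edges can be
#' rotated with `direction_origin_deg`.
#'
#' @param n_direction_bins Number of direction bins (default 6).
#' @param direction_origin_deg Rotation of the first bin edge in degrees
#'   (default 0, i.e. bins `[0,60), [60,120), ...`).
#' @param amplitude_edges Inner edges of the amplitude bands in degrees
#'   (default `c(5, 10)`).
#' @return A `polar_binning` list.
#' @export
polar_binning <- function(n_direction_bins = 6, direction_origin_deg = 0,
                          amplitude_edges = c(5, 10)) {
  if (n_direction_bins < 1 || any(diff(c(0, amplitude_edges)) <= 0))
    fv_input_error("invalid binning")
  structure(
    list(n_direction_bins = as.integer(n_direction_bins),
         direction_bin_width = 360 / n_direction_bins,
         direction_origin_deg = direction_origin_deg,
         amplitude_edges = amplitude_edges,
         amplitude_labels = c("short", "medium", "long")),
    class = "polar_binning"
  )
}

#' Detect saccades from gaze kinematics
#'
#' Threshold-based detection on a calibrated, smoothed trace:
#' \enumerate{
#'   \item contiguous runs with speed above `v_candidate` (100 deg/s) are
#'     candidate saccades;
#'   \item a candidate is kept only if the absolute acceleration within it
#'     exceeds `a_confirm` (5000 deg/s^2);
#'   \item onset is the first sample within `onset_search_ms` (100 ms)
#'     before the peak-velocity sample where speed exceeds `v_onset`
#'     (20 deg/s); if no sample in the window does (pathological), the
#'     window start is used and the saccade flagged;
#'   \item offset mirrors the onset rule: the first sample after the peak
#'     where speed falls below `v_onset`, capped at 100 ms past the peak;
#'   \item candidates whose onsets are separated by less than
#'     `merge_gap_ms` (50 ms) are merged to suppress double detection of
#'     dynamic overshoots.
#' }
#' Start and end positions are read from the (smoothed) trace at the onset
#' and offset samples.
#'
#' @param kin A `kin_trace` from [kinematics()].
#' @param trace The matching [eye_trace()] in degrees.
#' @param v_candidate Candidate speed threshold, deg/s (default 100).
#' @param a_confirm Confirmation acceleration threshold, deg/s^2
#'   (absolute value; default 5000).
#' @param v_onset Onset/offset speed threshold, deg/s (default 20).
#' @param onset_search_ms Pre-peak onset search window, ms (default 100).
#' @param merge_gap_ms Minimum onset separation before merging, ms
#'   (default 50).
#' @return Data frame with one row per saccade: `t_onset`, `t_offset`,
#'   `x0`, `y0`, `x1`, `y1`, `amplitude`, `direction` (degrees in
#'   `[0, 360)`), `peak_velocity`, `peak_accel`, `onset_flagged`.
#' @export
detect_saccades <- function(kin, trace, v_candidate = 100, a_confirm = 5000,
                            v_onset = 20, onset_search_ms = 100,
                            merge_gap_ms = 50) {
  stopifnot(inherits(kin, "kin_trace"), inherits(trace, "eye_trace"))
  if (trace$unit != "degrees") fv_input_error("trace must be in degrees")
  if (length(kin$t) != length(trace$t))
    fv_input_error("kinematics and trace are not aligned")
  if (v_candidate <= 0 || a_confirm <= 0 || v_onset <= 0)
    fv_input_error("thresholds must be positive")
  tt <- kin$t
  sp <- kin$speed
  ac <- kin$accel
  n <- length(tt)
  above <- sp > v_candidate
  if (!any(above)) return(empty_saccades())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  a <- starts[r$values]
  b <- ends[r$values]
  keep <- vapply(seq_along(a),
                 function(k) max(abs(ac[a[k]:b[k]])) > a_confirm,
                 logical(1))
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) return(empty_saccades())
  onset <- integer(length(a)); offset <- integer(length(a))
  pk <- integer(length(a)); flagged <- logical(length(a))
  w_smp <- as.integer(round(onset_search_ms / median(diff(tt))))
  for (k in seq_along(a)) {
    pk[k] <- a[k] - 1L + which.max(sp[a[k]:b[k]])
    w0 <- max(1L, pk[k] - w_smp)
    pre <- w0 - 1L + which(sp[w0:pk[k]] > v_onset)
    if (length(pre) > 0L) {
      onset[k] <- pre[1]
    } else {
      onset[k] <- w0
      flagged[k] <- TRUE
    }
    cap <- min(n, pk[k] + w_smp)
    post <- if (pk[k] < n) pk[k] + which(sp[(pk[k] + 1L):cap] < v_onset)
            else integer(0)
    offset[k] <- if (length(post) > 0L) post[1] else cap
  }
  # merge candidates whose onsets are closer than merge_gap_ms (and any
  # remaining overlaps), keeping the larger peak
  ord <- order(tt[onset])
  onset <- onset[ord]; offset <- offset[ord]; pk <- pk[ord]
  flagged <- flagged[ord]
  mo <- onset[1]; mf <- offset[1]; mp <- pk[1]; mg <- flagged[1]
  res <- list()
  for (k in seq_along(onset)[-1]) {
    if (tt[onset[k]] - tt[mo] < merge_gap_ms || onset[k] <= mf) {
      mf <- max(mf, offset[k])
      if (sp[pk[k]] > sp[mp]) mp <- pk[k]
      mg <- mg || flagged[k]
    } else {
      res[[length(res) + 1L]] <- c(mo, mf, mp, mg)
      mo <- onset[k]; mf <- offset[k]; mp <- pk[k]; mg <- flagged[k]
    }
  }
  res[[length(res) + 1L]] <- c(mo, mf, mp, mg)
  m <- do.call(rbind, res)
  onset <- m[, 1]; offset <- m[, 2]; pk <- m[, 3]; flagged <- as.logical(m[, 4])
  dx <- trace$x[offset] - trace$x[onset]
  dy <- trace$y[offset] - trace$y[onset]
  amp <- sqrt(dx^2 + dy^2)
  dir <- (atan2(dy, dx) * 180 / pi) %% 360
  dir[amp == 0] <- NA_real_
  data.frame(
    t_onset = tt[onset], t_offset = tt[offset],
    x0 = trace$x[onset], y0 = trace$y[onset],
    x1 = trace$x[offset], y1 = trace$y[offset],
    amplitude = amp, direction = dir,
    peak_velocity = sp[pk],
    peak_accel = vapply(seq_along(onset),
                        function(k) max(abs(ac[onset[k]:offset[k]])),
                        numeric(1)),
    onset_flagged = flagged
  )
}

empty_saccades <- function() {
  data.frame(t_onset = numeric(0), t_offset = numeric(0),
             x0 = numeric(0), y0 = numeric(0),
             x1 = numeric(0), y1 = numeric(0),
             amplitude = numeric(0), direction = numeric(0),
             peak_velocity = numeric(0), peak_accel = numeric(0),
             onset_flagged = logical(0))
}

#' Saccade amplitude and direction
#'
#' Amplitude is the Euclidean distance between start and end position;
#' direction is `atan2(dy, dx)` mapped to `[0, 360)` degrees with 0 =
#' rightward and counterclockwise positive.
#'
#' @param s A one-row saccade data frame (or list) with `x0`, `y0`, `x1`,
#'   `y1`.
#' @return Named numeric vector `c(amplitude, direction)`.
#' @export
saccade_vector <- function(s) {
  dx <- s$x1 - s$x0
  dy <- s$y1 - s$y0
  amp <- sqrt(dx^2 + dy^2)
  if (any(amp == 0)) fv_input_error("degenerate saccade")
  c(amplitude = amp, direction = (atan2(dy, dx) * 180 / pi) %% 360)
}

#' Assign saccades to polar bins
#'
#' Maps each saccade to exactly one direction bin (`0 .. n-1`,
#' counterclockwise from the binning origin) and one amplitude band
#' (`short` / `medium` / `long`), using half-open intervals.
#'
#' @param saccades Saccade data frame with `amplitude` and `direction`.
#' @param binning A [polar_binning()].
#' @return The saccade data frame with added integer `dir_bin` and factor
#'   `amp_bin` columns.
#' @export
bin_saccades <- function(saccades, binning = polar_binning()) {
  stopifnot(inherits(binning, "polar_binning"))
  rel <- (saccades$direction - binning$direction_origin_deg) %% 360
  saccades$dir_bin <- as.integer(floor(rel / binning$direction_bin_width))
  saccades$dir_bin[saccades$dir_bin >= binning$n_direction_bins] <-
    binning$n_direction_bins - 1L  # guard direction == 360 after rounding
  saccades$amp_bin <- cut(saccades$amplitude,
                          breaks = c(0, binning$amplitude_edges, Inf),
                          labels = binning$amplitude_labels,
                          right = FALSE, include.lowest = TRUE)
  saccades
}
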