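#' Patch-stimulus grid geometry
#'
#' Geometry of the receptive-field mapping stimulus: a white square patch
#' flashed for 50 ms at each cell of a 6 x 6 checkerboard area spanning
#' 22 x 22 degrees. Cell centers divide the extent into equal strips per
#' axis; the 2 degree patch being smaller than the ~3.67 degree cell pitch
#' is a display property and does not enter the analysis geometry. Rows run
#' top to bottom (row 1 has the largest y), columns left to right.
#'
#' @param n_rows,n_cols Grid dimensions (default 6 x 6).
#' @param extent_deg Length-2 extent of the grid in degrees (default 22 x 22).
#' @param patch_deg Patch side in degrees (default 2; display only).
#' @param dt_ms Patch presentation time in ms (default 50).
#' @param origin Screen coordinates of the grid center in degrees.
#' @return A `stimulus_grid` list with a precomputed `centers` data frame
#'   (`row`, `col`, `x_deg`, `y_deg`).
#' @export
stimulus_grid <- function(n_rows = 6, n_cols = 6, extent_deg = c(22, 22),
                          patch_deg = 2, dt_ms = 50, origin = c(0, 0)) {
  if (dt_ms <= 0) fv_input_error("dt_ms must be positive")
  pitch_x <- extent_deg[1] / n_cols
  pitch_y <- extent_deg[2] / n_rows
  centers <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  centers$x_deg <- origin[1] + (centers$col - (n_cols + 1) / 2) * pitch_x
  centers$y_deg <- origin[2] + ((n_rows + 1) / 2 - centers$row) * pitch_y
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         extent_deg = extent_deg, patch_deg = patch_deg, dt_ms = dt_ms,
         origin = origin, centers = centers),
    class = "stimulus_grid"
  )
}

# number of spikes in each half-open window [a, b); spikes must be sorted
count_in_windows <- function(spikes, a, b) {
  findInterval(b, spikes, left.open = TRUE) -
    findInterval(a, spikes, left.open = TRUE)
}

#' Reverse-correlation receptive-field map
#'
#' For each grid cell, the map value is the mean firing rate evoked by that
#' cell's patch presentations after shifting by the response latency t':
#' C = (1/n) * (1000 / dt) * sum over the cell's n presentations of the
#' spike count in `[t_onset + t', t_onset + t' + dt)`, in Hz. Windows are
#' closed-open so a spike lands in exactly one adjacent window. Cells with
#' fewer than `min_reps` presentations are undefined (`NA`).
#'
#' @param spikes Sorted numeric vector of spike times in ms.
#' @param events Data frame of patch presentations with `t_onset_ms`,
#'   `row`, `col` (and optionally `duration_ms`).
#' @param grid A [stimulus_grid()].
#' @param latency_ms Response latency t' in ms subtracted before
#'   correlating (default 40, a typical collicular visual latency; see
#'   [estimate_latency()] for a data-driven alternative).
#' @param min_reps Minimum presentations per cell (default 5).
#' @return An `rf_map`: list with `rates` (n_rows x n_cols matrix, Hz),
#'   `n_per_cell`, `latency_ms`, `grid`.
#' @export
reverse_correlate_rf <- function(spikes, events, grid = stimulus_grid(),
                                 latency_ms = 40, min_reps = 5) {
  if (is.null(events) || nrow(events) == 0L) fv_input_error("no events")
  if (is.unsorted(spikes)) fv_input_error("unordered spikes")
  if (latency_ms < 0) fv_input_error("latency_ms must be >= 0")
  if (any(events$row < 1 | events$row > grid$n_rows |
          events$col < 1 | events$col > grid$n_cols))
    fv_input_error("event references a cell outside the grid")
  dt <- grid$dt_ms
  a <- events$t_onset_ms + latency_ms
  counts <- count_in_windows(spikes, a, a + dt)
  cell <- (events$col - 1L) * grid$n_rows + events$row
  n_per <- tabulate(cell, nbins = grid$n_rows * grid$n_cols)
  tot <- vapply(seq_len(grid$n_rows * grid$n_cols),
                function(i) sum(counts[cell == i]), numeric(1))
  rates <- ifelse(n_per >= min_reps, (tot / n_per) * (1000 / dt), NA_real_)
  structure(
    list(rates = matrix(rates, grid$n_rows, grid$n_cols),
         n_per_cell = matrix(n_per, grid$n_rows, grid$n_cols),
         latency_ms = latency_ms, grid = grid, min_reps = min_reps),
    class = "rf_map"
  )
}

#' @export
print.rf_map <- function(x, ...) {
  cat(sprintf("<rf_map> %dx%d, latency %g ms, peak %.1f Hz\n",
              nrow(x$rates), ncol(x$rates), x$latency_ms,
              suppressWarnings(max(x$rates, na.rm = TRUE))))
  invisible(x)
}

#' Receptive-field center
#'
#' The RF center is the centroid, in screen degrees, of the defined cells
#' whose rate is at least halfway from the baseline (median of defined
#' cells) to the peak. A flat map (peak equal to baseline) carries no RF.
#'
#' @param map An [reverse_correlate_rf()] result.
#' @return Named numeric `c(x_deg, y_deg)`.
#' @export
rf_center <- function(map) {
  r <- map$rates
  ok <- !is.na(r)
  if (!any(ok)) fv_input_error("no defined cells")
  baseline <- median(r[ok])
  peak <- max(r[ok])
  if (peak <= baseline) fv_input_error("no RF detected")
  thr <- baseline + 0.5 * (peak - baseline)
  sel <- ok & r >= thr
  ce <- map$grid$centers
  hot <- sel[cbind(ce$row, ce$col)]
  c(x_deg = mean(ce$x_deg[hot]), y_deg = mean(ce$y_deg[hot]))
}

#' Peri-event time histogram
#'
#' Event-aligned spike histogram: spike counts in bins of `bin_ms` across
#' `window` around each alignment time, divided by
#' `n_events * bin_ms / 1000` to give a rate in Hz.
#'
#' @param spikes Sorted spike times in ms.
#' @param align_times Event times (e.g. saccade onsets) in ms.
#' @param window Length-2 window around each event in ms
#'   (default `c(-100, 300)`).
#' @param bin_ms Bin width in ms (default 10).
#' @return Data frame with `t` (bin centers relative to the event, ms),
#'   `count` (summed spikes) and `rate` (Hz).
#' @export
psth <- function(spikes, align_times, window = c(-100, 300), bin_ms = 10) {
  if (length(align_times) == 0L) fv_input_error("empty align_times")
  if (bin_ms <= 0) fv_input_error("bin_ms must be positive")
  if (is.unsorted(spikes)) fv_input_error("unordered spikes")
  edges <- seq(window[1], window[2], by = bin_ms)
  if (length(edges) < 2L) fv_input_error("window shorter than one bin")
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  for (a in align_times) {
    lo <- findInterval(a + edges[1], spikes, left.open = TRUE)
    hi <- findInterval(a + edges[nb + 1L], spikes, left.open = TRUE)
    if (hi > lo) {
      rel <- spikes[(lo + 1L):hi] - a
      bin <- pmin(nb, 1L + floor((rel - edges[1]) / bin_ms))
      counts <- counts + tabulate(bin, nbins = nb)
    }
  }
  data.frame(t = edges[-(nb + 1L)] + bin_ms / 2, count = counts,
             rate = counts / (length(align_times) * bin_ms / 1000))
}

#' Data-driven response latency estimate
#'
#' Grid-searches the latency t' in 1 ms steps over `search`, computing the
#' RF map at each shift and scoring it by the peak z-score of the defined
#' cell rates ((max - mean) / sd). The t' with the highest score is
#' returned. When no shift produces a clearly structured map (best score
#' below `z_min`), the estimate is degenerate: the fixed default is
#' returned with `flagged = TRUE`.
#'
#' @param spikes Sorted spike times in ms.
#' @param events Patch presentation events (see [reverse_correlate_rf()]).
#' @param grid A [stimulus_grid()].
#' @param search Length-2 search range in ms (default `c(0, 100)`).
#' @param step_ms Search step (default 1 ms).
#' @param default_ms Fallback latency (default 40 ms).
#' @param z_min Minimum peak z-score for a non-degenerate estimate
#'   (default 3.5).
#' @param min_reps Minimum presentations per cell (default 5).
#' @return List with `latency_ms`, `z`, `flagged`, `default_ms`.
#' @export
estimate_latency <- function(spikes, events, grid = stimulus_grid(),
                             search = c(0, 100), step_ms = 1,
                             default_ms = 40, z_min = 3.5, min_reps = 5) {
  if (is.null(events) || nrow(events) < min_reps)
    fv_input_error("too few events")
  shifts <- seq(search[1], search[2], by = step_ms)
  best_z <- -Inf
  best_t <- default_ms
  for (tp in shifts) {
    m <- reverse_correlate_rf(spikes, events, grid, latency_ms = tp,
                              min_reps = min_reps)
    r <- m$rates[!is.na(m$rates)]
    if (length(r) < 2L) next
    s <- sd(r)
    if (s == 0) next
    z <- (max(r) - mean(r)) / s
    if (z > best_z) {
      best_z <- z
      best_t <- tp
    }
  }
  flagged <- !is.finite(best_z) || best_z < z_min
  list(latency_ms = if (flagged) default_ms else best_t,
       z = best_z, flagged = flagged, default_ms = default_ms)
}
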