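#' Peri-saccadic motor-field map
#'
#' Correlates spiking with the vectors of spontaneous saccades: for every
#' (direction, amplitude) bin, the rate is the total spike count within
#' `window` around the onsets of the bin's saccades divided by
#' `count * window length` (Hz). The default window runs from 50 ms before
#' to 50 ms after saccade onset. Bins with fewer than `min_count` saccades
#' are undefined. Peri-saccadic windows of saccades closer than the window
#' length may double-count spikes; this is the plain reading of a fixed
#' window around every onset.
#'
#' @param spikes Sorted spike times in ms.
#' @param saccades Saccade data frame (from [detect_saccades()]), binned or
#'   not; binning is (re)computed with `binning`.
#' @param binning A [polar_binning()].
#' @param window Length-2 window around saccade onset in ms
#'   (default `c(-50, 50)`).
#' @param min_count Minimum saccades per bin (default 3).
#' @return An `mf_map`: list with `rates` and `counts`
#'   (n_direction_bins x 3 matrices; rows are direction bins 0..n-1,
#'   columns short/medium/long), `window`, `preferred` (named vector
#'   `dir_bin`, `amp_bin` of the argmax over defined bins, ties resolved
#'   toward the lower amplitude band then the lower direction index),
#'   `binning`.
#' @export
map_motor_field <- function(spikes, saccades, binning = polar_binning(),
                            window = c(-50, 50), min_count = 3) {
  if (is.null(saccades) || nrow(saccades) == 0L)
    fv_input_error("no saccades to map")
  if (is.unsorted(spikes)) fv_input_error("unordered spikes")
  if (diff(window) <= 0) fv_input_error("window must have positive length")
  saccades <- bin_saccades(saccades, binning)
  win_s <- diff(window) / 1000
  nd <- binning$n_direction_bins
  na_ <- length(binning$amplitude_labels)
  counts <- matrix(0L, nd, na_,
                   dimnames = list(paste0("dir", seq_len(nd) - 1L),
                                   binning$amplitude_labels))
  spk <- matrix(0, nd, na_, dimnames = dimnames(counts))
  nsp <- count_in_windows(spikes, saccades$t_onset + window[1],
                          saccades$t_onset + window[2])
  for (k in seq_len(nrow(saccades))) {
    i <- saccades$dir_bin[k] + 1L
    j <- as.integer(saccades$amp_bin[k])
    counts[i, j] <- counts[i, j] + 1L
    spk[i, j] <- spk[i, j] + nsp[k]
  }
  rates <- ifelse(counts >= min_count, spk / (counts * win_s), NA_real_)
  preferred <- c(dir_bin = NA_integer_, amp_bin = NA_integer_)
  if (any(!is.na(rates))) {
    best <- -Inf
    for (j in seq_len(na_)) {      # lower amplitude band wins ties
      for (i in seq_len(nd)) {     # then lower direction index
        if (!is.na(rates[i, j]) && rates[i, j] > best) {
          best <- rates[i, j]
          preferred <- c(dir_bin = i - 1L, amp_bin = j)
        }
      }
    }
  }
  structure(
    list(rates = rates, counts = counts, window = window,
         preferred = preferred, binning = binning, min_count = min_count),
    class = "mf_map"
  )
}

#' @export
print.mf_map <- function(x, ...) {
  cat(sprintf(
    "<mf_map> %d directions x %d amplitudes, window [%g, %g] ms\n",
    nrow(x$rates), ncol(x$rates), x$window[1], x$window[2]))
  if (!is.na(x$preferred["dir_bin"]))
    cat(sprintf("  preferred: dir_bin %d, %s\n", x$preferred["dir_bin"],
                colnames(x$rates)[x$preferred["amp_bin"]]))
  invisible(x)
}

#' Visual-to-motor response ratio
#'
#' Ratio of a channel's mean response to stimuli in its receptive field to
#' its mean peri-saccadic activity. The visual rate averages the RF cells
#' at or above half the peak rate; the motor rate averages the defined
#' motor-field bins at or above half the peak bin rate. The ratio decreases
#' with depth in the superior colliculus, where superficial neurons are
#' visual-dominant and deep neurons saccade-dominant.
#'
#' @param rf An `rf_map`.
#' @param mf An `mf_map`.
#' @return List with `visual_rate`, `motor_rate` (Hz), `ratio`
#'   (`NA` with `undefined = TRUE` when the motor rate is zero).
#' @export
visuomotor_index <- function(rf, mf) {
  rv <- rf$rates[!is.na(rf$rates)]
  mv <- mf$rates[!is.na(mf$rates)]
  if (length(rv) == 0L || length(mv) == 0L)
    fv_input_error("undefined map peaks")
  visual <- mean(rv[rv >= 0.5 * max(rv)])
  motor <- mean(mv[mv >= 0.5 * max(mv)])
  if (motor == 0) {
    list(visual_rate = visual, motor_rate = motor, ratio = NA_real_,
         undefined = TRUE)
  } else {
    list(visual_rate = visual, motor_rate = motor, ratio = visual / motor,
         undefined = FALSE)
  }
}

#' Pairwise field-center distances
#'
#' Quantifies how much receptive (or motor) fields across channels overlap
#' by the pairwise Euclidean distances between their centers.
#'
#' @param centers Two-column matrix (or data frame) of field centers in
#'   degrees, one row per channel.
#' @return List with `distances` (full symmetric matrix, degrees) and
#'   `mean_distance` (mean over distinct pairs).
#' @export
field_overlap <- function(centers) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 2L) fv_input_error("need at least 2 centers")
  d <- as.matrix(stats::dist(centers))
  list(distances = d, mean_distance = mean(d[upper.tri(d)]))
}
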