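#' Synthetic neuron specification
#'
#' Latent response parameters for one simulated channel: a baseline rate, a
#' Gaussian visual receptive field (center, width, peak rate, response
#' latency) driving responses to patch presentations, and a saccade-vector
#' tuned peri-saccadic burst (preferred direction/amplitude, tuning widths,
#' burst peak and temporal width). Defaults describe a vigorous collicular
#' visuomotor neuron with an upper-right RF and a matching motor field.
#'
#' @param baseline_hz Background Poisson rate (default 10 Hz).
#' @param rf_center RF center in screen degrees (default `c(5.5, 5.5)`, a
#'   grid cell center of the default 6 x 6 / 22 degree stimulus grid).
#' @param rf_sigma_deg Spatial SD of the RF (default 2).
#' @param rf_peak_hz Added rate for a patch at the RF center (default 100).
#' @param latency_ms Visual response latency (default 40).
#' @param mf_dir_deg,mf_amp_deg Preferred saccade direction (degrees) and
#'   amplitude (default 33 degrees, 7.5 degrees -- upper-right, medium).
#' @param mf_sigma_dir_deg,mf_sigma_amp_deg Tuning widths (default 25
#'   degrees and 3 degrees).
#' @param burst_peak_hz Peak added rate of the peri-saccadic burst for a
#'   saccade at the preferred vector (default 200 Hz).
#' @param burst_sd_ms Temporal SD of the burst around saccade onset
#'   (default 15 ms).
#' @return A `neuron_spec` list.
#' @export
neuron_spec <- function(baseline_hz = 10, rf_center = c(5.5, 5.5),
                        rf_sigma_deg = 2, rf_peak_hz = 100, latency_ms = 40,
                        mf_dir_deg = 33, mf_amp_deg = 7.5,
                        mf_sigma_dir_deg = 25, mf_sigma_amp_deg = 3,
                        burst_peak_hz = 200, burst_sd_ms = 15) {
  if (baseline_hz < 0 || rf_peak_hz < 0 || burst_peak_hz < 0)
    fv_input_error("negative rate parameters")
  structure(as.list(environment()), class = "neuron_spec")
}

#' Synthetic session configuration
#'
#' Holds every latent parameter of the simulator: the tracker model (true
#' per-axis gain/offset and voltage noise), the free-viewing behavior
#' (log-normal fixation durations, probability of attending the active
#' stimulus, fixation scatter, minimum-jerk main-sequence saccades), the
#' block layout (five 2-minute calibration epochs, an RF-mapping block with
#' a given number of repetitions per grid cell, a free-viewing block), and
#' the per-channel neuron specifications.
#'
#' @param seed Default RNG seed for [simulate_session()].
#' @param rate_hz Eye sampling rate, 120 (video tracker) or 1000 (digitized
#'   with the neural data).
#' @param gain,offset True tracker calibration, degrees = gain * volts +
#'   offset, length-2 (x, y).
#' @param noise_v_sd Additive white noise on the voltage trace (V).
#' @param pos_noise_deg_sd Additive gaze position noise in degrees.
#' @param fix_median_ms,fix_sdlog,fix_min_ms Log-normal fixation duration:
#'   median 700 ms, log-SD 0.4, truncated below at 200 ms.
#' @param p_attend Probability that a fixation targets the active
#'   calibration stimulus (or the fixation point during RF mapping) rather
#'   than a random screen location (default 0.6).
#' @param scatter_deg_sd SD of fixation landing scatter around the attended
#'   target, degrees (default 1.5, matching the 1-2 degree cluster widths
#'   seen in practice).
#' @param mainseq_d0_ms,mainseq_d1_ms_per_deg Main-sequence duration model
#'   `D = d0 + d1 * amplitude` in ms (defaults 20 and 2).
#' @param screen_deg Screen extent (horizontal, vertical) in degrees
#'   (default `c(56, 31)`).
#' @param calibration_locations Calibration stimulus locations (n x 2,
#'   degrees); `NULL` or `calibration_epoch_s = 0` drops the block.
#' @param calibration_epoch_s Seconds per calibration epoch (default 120).
#' @param grid [stimulus_grid()] for the RF block.
#' @param rf_reps Patch repetitions per grid cell (default 10; 0 drops the
#'   block).
#' @param rf_gap_ms Gap between column trials in the RF block (default 300).
#' @param freeview_s Free-viewing block duration in seconds (default 300).
#' @param neurons List of [neuron_spec()]s, one per channel.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1, rate_hz = 1000,
                         gain = c(x = 5, y = 5), offset = c(x = 2, y = -1),
                         noise_v_sd = 0.05, pos_noise_deg_sd = 0.02,
                         fix_median_ms = 700, fix_sdlog = 0.4,
                         fix_min_ms = 200,
                         p_attend = 0.6, scatter_deg_sd = 1.5,
                         mainseq_d0_ms = 20, mainseq_d1_ms_per_deg = 2,
                         screen_deg = c(56, 31),
                         calibration_locations = default_calibration_locations(),
                         calibration_epoch_s = 120,
                         grid = stimulus_grid(), rf_reps = 10,
                         rf_gap_ms = 300, freeview_s = 300,
                         neurons = list(neuron_spec())) {
  if (p_attend < 0 || p_attend > 1) fv_input_error("p_attend must be in [0,1]")
  if (noise_v_sd < 0 || pos_noise_deg_sd < 0 || scatter_deg_sd < 0)
    fv_input_error("noise SDs must be non-negative")
  if (any(gain == 0)) fv_input_error("gain must be non-zero")
  structure(as.list(environment()), class = "synth_config")
}

# block boundaries in ms: calibration, RF mapping, free viewing
session_blocks <- function(config) {
  cal_ms <- if (!is.null(config$calibration_locations) &&
                config$calibration_epoch_s > 0)
    nrow(as.matrix(config$calibration_locations)) *
      config$calibration_epoch_s * 1000 else 0
  trial_ms <- config$grid$n_rows * config$grid$dt_ms + config$rf_gap_ms
  rf_ms <- config$rf_reps * config$grid$n_cols * trial_ms
  fv_ms <- config$freeview_s * 1000
  list(cal = c(0, cal_ms), rf = c(cal_ms, cal_ms + rf_ms),
       fv = c(cal_ms + rf_ms, cal_ms + rf_ms + fv_ms),
       total_ms = cal_ms + rf_ms + fv_ms, rf_trial_ms = trial_ms)
}

# minimum-jerk position profile on [0, 1]
mj_profile <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

#' Analytic peak velocity of a minimum-jerk saccade
#'
#' For a minimum-jerk trajectory of amplitude `amp_deg` and duration
#' `dur_ms`, the peak velocity is `1.875 * amp / dur` (reached at
#' midflight).
#'
#' @param amp_deg Saccade amplitude, degrees.
#' @param dur_ms Saccade duration, ms.
#' @return Peak velocity in deg/s.
#' @export
minimum_jerk_peak_velocity <- function(amp_deg, dur_ms) {
  1.875 * amp_deg / (dur_ms / 1000)
}

#' Simulate free-viewing gaze
#'
#' Generates a calibrated gaze trace of alternating fixations and
#' minimum-jerk saccades over the session's block layout. During a
#' calibration epoch each fixation targets the active stimulus with
#' probability `p_attend` (with Gaussian landing scatter) and a uniform
#' random screen location otherwise; during the RF block the attended
#' target is the central fixation point; during free viewing all targets
#' are uniform over the screen. Saccade durations follow the linear main
#' sequence `D = d0 + d1 * A`, so peak velocity is `1.875 * A / D`.
#' Additive Gaussian position noise is applied to every sample.
#'
#' @param config A [synth_config()].
#' @param seed Optional seed; `NULL` continues the current RNG stream (as
#'   done inside [simulate_session()]).
#' @return List with `trace` (an [eye_trace()] in degrees), `fixations` and
#'   `saccades` ground-truth data frames, and `blocks`.
#' @export
simulate_gaze <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- session_blocks(config)
  total <- blocks$total_ms
  if (total <= 0) fv_input_error("zero-length session")
  cal_locs <- if (blocks$cal[2] > blocks$cal[1])
    as.matrix(config$calibration_locations) else NULL
  epoch_ms <- config$calibration_epoch_s * 1000
  half_w <- config$screen_deg[1] / 2
  half_h <- config$screen_deg[2] / 2
  pick_target <- function(t) {
    attended <- FALSE
    epoch <- NA_integer_
    if (!is.null(cal_locs) && t < blocks$cal[2]) {
      epoch <- min(nrow(cal_locs), 1L + floor(t / epoch_ms))
      if (runif(1) < config$p_attend) {
        tgt <- cal_locs[epoch, ] + rnorm(2, 0, config$scatter_deg_sd)
        attended <- TRUE
      } else {
        tgt <- c(runif(1, -half_w, half_w), runif(1, -half_h, half_h))
      }
    } else if (t < blocks$rf[2]) {
      if (runif(1) < config$p_attend) {
        tgt <- rnorm(2, 0, config$scatter_deg_sd)
        attended <- TRUE
      } else {
        tgt <- c(runif(1, -half_w, half_w), runif(1, -half_h, half_h))
      }
    } else {
      tgt <- c(runif(1, -half_w, half_w), runif(1, -half_h, half_h))
    }
    list(xy = tgt, attended = attended, epoch = epoch)
  }
  # event sequence: alternating fixation / saccade segments
  cap <- ceiling(total / (config$fix_min_ms)) + 4L
  seg_t0 <- numeric(cap); seg_dur <- numeric(cap)
  seg_x0 <- numeric(cap); seg_y0 <- numeric(cap)
  seg_dx <- numeric(cap); seg_dy <- numeric(cap)
  fx <- list(t_start = numeric(cap), t_end = numeric(cap),
             x = numeric(cap), y = numeric(cap),
             epoch = integer(cap), attended = logical(cap))
  sc <- list(t_onset = numeric(cap), t_offset = numeric(cap),
             x0 = numeric(cap), y0 = numeric(cap),
             x1 = numeric(cap), y1 = numeric(cap),
             amplitude = numeric(cap), direction = numeric(cap),
             duration_ms = numeric(cap), peak_velocity = numeric(cap))
  ns <- 0L; nf <- 0L; nsc <- 0L
  t_cur <- 0
  first <- pick_target(0)
  pos <- first$xy
  while (t_cur < total) {
    d <- max(config$fix_min_ms,
             rlnorm(1, meanlog = log(config$fix_median_ms),
                    sdlog = config$fix_sdlog))
    d <- min(d, total - t_cur)
    ns <- ns + 1L
    seg_t0[ns] <- t_cur; seg_dur[ns] <- d
    seg_x0[ns] <- pos[1]; seg_y0[ns] <- pos[2]
    nf <- nf + 1L
    fx$t_start[nf] <- t_cur; fx$t_end[nf] <- t_cur + d
    fx$x[nf] <- pos[1]; fx$y[nf] <- pos[2]
    t_cur <- t_cur + d
    if (t_cur >= total) break
    nxt <- pick_target(t_cur)
    fx$epoch[nf + 1L] <- nxt$epoch      # filled for the upcoming fixation
    fx$attended[nf + 1L] <- nxt$attended
    amp <- sqrt(sum((nxt$xy - pos)^2))
    if (amp < 1e-9) next                 # same spot; extend with a new fixation
    dur <- config$mainseq_d0_ms + config$mainseq_d1_ms_per_deg * amp
    ns <- ns + 1L
    seg_t0[ns] <- t_cur; seg_dur[ns] <- dur
    seg_x0[ns] <- pos[1]; seg_y0[ns] <- pos[2]
    seg_dx[ns] <- nxt$xy[1] - pos[1]; seg_dy[ns] <- nxt$xy[2] - pos[2]
    nsc <- nsc + 1L
    sc$t_onset[nsc] <- t_cur; sc$t_offset[nsc] <- t_cur + dur
    sc$x0[nsc] <- pos[1]; sc$y0[nsc] <- pos[2]
    sc$x1[nsc] <- nxt$xy[1]; sc$y1[nsc] <- nxt$xy[2]
    sc$amplitude[nsc] <- amp
    sc$direction[nsc] <- (atan2(nxt$xy[2] - pos[2],
                                nxt$xy[1] - pos[1]) * 180 / pi) %% 360
    sc$duration_ms[nsc] <- dur
    sc$peak_velocity[nsc] <- minimum_jerk_peak_velocity(amp, dur)
    t_cur <- t_cur + dur
    pos <- nxt$xy
  }
  # epoch/attended of the very first fixation
  fx$epoch[1] <- first$epoch
  fx$attended[1] <- first$attended
  fixations <- data.frame(t_start = fx$t_start[seq_len(nf)],
                          t_end = fx$t_end[seq_len(nf)],
                          x = fx$x[seq_len(nf)], y = fx$y[seq_len(nf)],
                          epoch = fx$epoch[seq_len(nf)],
                          attended = fx$attended[seq_len(nf)])
  fixations$epoch[fixations$epoch == 0L] <- NA_integer_
  saccades <- as.data.frame(lapply(sc, function(v) v[seq_len(nsc)]))
  # sample the piecewise trajectory
  dt_ms <- 1000 / config$rate_hz
  tgrid <- seq(0, total - dt_ms, by = dt_ms)
  idx <- findInterval(tgrid, seg_t0[seq_len(ns)])
  tau <- pmin(1, pmax(0, (tgrid - seg_t0[idx]) / seg_dur[idx]))
  s <- mj_profile(tau)
  xg <- seg_x0[idx] + seg_dx[idx] * s + rnorm(length(tgrid), 0,
                                              config$pos_noise_deg_sd)
  yg <- seg_y0[idx] + seg_dy[idx] * s + rnorm(length(tgrid), 0,
                                              config$pos_noise_deg_sd)
  trace <- eye_trace(tgrid, xg, yg, unit = "degrees",
                     rate_hz = config$rate_hz)
  list(trace = trace, fixations = fixations, saccades = saccades,
       blocks = blocks)
}

#' Convert a calibrated trace to raw tracker volts
#'
#' Inverts the true affine tracker model per axis
#' (volts = (deg - offset) / gain) and adds white voltage noise. The unit
#' tag flips to volts.
#'
#' @param trace An [eye_trace()] in degrees.
#' @param gain,offset True calibration, length-2 (x, y).
#' @param noise_sd Voltage noise SD (V).
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return An `eye_trace` in volts.
#' @export
degrees_to_volts <- function(trace, gain = c(5, 5), offset = c(2, -1),
                             noise_sd = 0.05, seed = NULL) {
  stopifnot(inherits(trace, "eye_trace"))
  if (trace$unit != "degrees") fv_input_error("trace must be in degrees")
  if (any(gain == 0)) fv_input_error("gain must be non-zero")
  if (!is.null(seed)) set.seed(seed)
  n <- length(trace$t)
  trace$x <- (trace$x - offset[1]) / gain[1] +
    if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  trace$y <- (trace$y - offset[2]) / gain[2] +
    if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  trace$unit <- "volts"
  trace
}

# RF-block patch presentation schedule: every repetition presents each of
# the grid's columns once (random column order), each column trial flashing
# the six row cells for dt_ms each in random row order
rf_event_schedule <- function(config, t0_ms) {
  g <- config$grid
  if (config$rf_reps <= 0)
    return(data.frame(t_onset_ms = numeric(0), row = integer(0),
                      col = integer(0), duration_ms = numeric(0)))
  trial_ms <- session_blocks(config)$rf_trial_ms
  onset <- integer(0); rowv <- integer(0); colv <- integer(0)
  k <- 0L
  for (rep in seq_len(config$rf_reps)) {
    for (col in sample(g$n_cols)) {
      t_trial <- t0_ms + k * trial_ms
      rows <- sample(g$n_rows)
      onset <- c(onset, t_trial + (seq_len(g$n_rows) - 1L) * g$dt_ms)
      rowv <- c(rowv, rows)
      colv <- c(colv, rep(col, g$n_rows))
      k <- k + 1L
    }
  }
  data.frame(t_onset_ms = onset, row = rowv, col = colv,
             duration_ms = g$dt_ms)
}

#' Simulate spike trains by Poisson thinning
#'
#' Generates one inhomogeneous Poisson spike train per channel. The rate at
#' time t is the channel's baseline, plus a visual term while a patch is on
#' (shifted by the response latency, scaled by the Gaussian RF evaluated at
#' the patch center), plus a motor term: a temporal Gaussian bump centered
#' on every saccade onset, scaled by the Gaussian vector tuning of the
#' saccade relative to the preferred (direction, amplitude). Spikes are
#' drawn by thinning a homogeneous Poisson process at the maximal rate,
#' which is exact and seedable.
#'
#' @param config A [synth_config()] supplying the channel specs.
#' @param ground_truth List with at least `saccades` (true saccade table)
#'   and `duration_ms` (session length).
#' @param events RF patch presentation events (possibly empty).
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return Named list of sorted spike-time vectors (ms), one per channel
#'   (`ch01`, `ch02`, ...).
#' @export
simulate_spikes <- function(config, ground_truth, events, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  total <- ground_truth$duration_ms
  sac <- ground_truth$saccades
  g <- config$grid
  have_events <- !is.null(events) && nrow(events) > 0L
  if (have_events) {
    ev_onset <- events$t_onset_ms
    centers <- g$centers
    key <- paste(events$row, events$col)
    ckey <- paste(centers$row, centers$col)
    ev_x <- centers$x_deg[match(key, ckey)]
    ev_y <- centers$y_deg[match(key, ckey)]
  }
  out <- vector("list", length(config$neurons))
  names(out) <- sprintf("ch%02d", seq_along(config$neurons))
  for (ci in seq_along(config$neurons)) {
    ns <- config$neurons[[ci]]
    if (have_events) {
      d2 <- (ev_x - ns$rf_center[1])^2 + (ev_y - ns$rf_center[2])^2
      w_ev <- ns$rf_peak_hz * exp(-d2 / (2 * ns$rf_sigma_deg^2))
    } else w_ev <- numeric(0)
    if (!is.null(sac) && nrow(sac) > 0L) {
      ddir <- ((sac$direction - ns$mf_dir_deg + 180) %% 360) - 180
      damp <- sac$amplitude - ns$mf_amp_deg
      w_sac <- ns$burst_peak_hz *
        exp(-0.5 * ((ddir / ns$mf_sigma_dir_deg)^2 +
                      (damp / ns$mf_sigma_amp_deg)^2))
      onsets <- sac$t_onset
    } else {
      w_sac <- numeric(0); onsets <- numeric(0)
    }
    rmax <- ns$baseline_hz +
      (if (length(w_ev)) max(w_ev) else 0) +
      (if (length(w_sac)) max(w_sac) else 0)
    if (rmax <= 0) { out[[ci]] <- numeric(0); next }
    m <- rpois(1, rmax * total / 1000)
    u <- sort(runif(m, 0, total))
    rate <- rep(ns$baseline_hz, m)
    if (have_events && m > 0) {
      shift <- u - ns$latency_ms
      i <- findInterval(shift, ev_onset)
      ok <- i >= 1L
      ii <- pmax(i, 1L)
      ok <- ok & shift < ev_onset[ii] + g$dt_ms
      rate <- rate + ifelse(ok, w_ev[ii], 0)
    }
    if (length(onsets) > 0L && m > 0) {
      j <- findInterval(u, onsets)
      for (off in 0:1) {
        jj <- j + off
        valid <- jj >= 1L & jj <= length(onsets)
        jj <- pmax(pmin(jj, length(onsets)), 1L)
        dt_on <- u - onsets[jj]
        gauss <- exp(-0.5 * (dt_on / ns$burst_sd_ms)^2)
        gauss[abs(dt_on) > 5 * ns$burst_sd_ms] <- 0
        rate <- rate + ifelse(valid, w_sac[jj] * gauss, 0)
      }
    }
    out[[ci]] <- u[runif(m) < rate / rmax]
  }
  out
}

#' Simulate a complete session with ground truth
#'
#' Composes the calibration, RF-mapping, and free-viewing blocks into a
#' full synthetic session: a calibrated gaze trace, its raw voltage
#' counterpart under the true tracker model, the calibration stimulus
#' schedule, the RF patch events, per-channel spike trains, and a ground
#' truth sidecar carrying every latent parameter that the analysis modules
#' are expected to recover. A fixed seed makes the whole bundle
#' reproducible bit for bit.
#'
#' @param config A [synth_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A `session_bundle`: list with `trace_volts`, `trace_deg`,
#'   `schedule`, `rf_events`, `spikes`, `ground_truth`, `config`.
#' @export
simulate_session <- function(config = synth_config(), seed = config$seed) {
  set.seed(seed)
  blocks <- session_blocks(config)
  if (blocks$total_ms <= 0) fv_input_error("zero-length session")
  schedule <- if (blocks$cal[2] > blocks$cal[1])
    calibration_schedule(config$calibration_locations,
                         epoch_s = config$calibration_epoch_s) else NULL
  rf_events <- rf_event_schedule(config, blocks$rf[1])
  gz <- simulate_gaze(config)
  trace_volts <- degrees_to_volts(gz$trace, config$gain, config$offset,
                                  config$noise_v_sd)
  ground_truth <- list(
    fixations = gz$fixations,
    saccades = gz$saccades,
    calibration = list(gain = config$gain, offset = config$offset),
    neurons = config$neurons,
    blocks = blocks,
    duration_ms = blocks$total_ms
  )
  spikes <- simulate_spikes(config, ground_truth, rf_events)
  structure(
    list(trace_volts = trace_volts, trace_deg = gz$trace,
         schedule = schedule, rf_events = rf_events, spikes = spikes,
         ground_truth = ground_truth, config = config, seed = seed),
    class = "session_bundle"
  )
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf(
    "<session_bundle> %.0f s @ %g Hz, %d channels, %d RF events, %d saccades\n",
    x$ground_truth$duration_ms / 1000, x$config$rate_hz,
    length(x$spikes), nrow(x$rf_events), nrow(x$ground_truth$saccades)))
  invisible(x)
}

#' Depth-layered 16-channel session configuration
#'
#' Study condition emulating a perpendicular linear-array penetration of
#' the superior colliculus: all channels share the same RF center and
#' preferred saccade vector (overlapping fields), while the visual peak
#' rate falls and the motor burst rises geometrically with channel depth,
#' so the visual-to-motor response ratio decreases monotonically from the
#' most superficial to the deepest channel.
#'
#' The gradient is geometric (uniform steps on a log scale) and its span is
#' chosen so that the expected step between adjacent channels is large
#' relative to the sampling error of the per-channel rate estimates at the
#' default session sizes (80 repetitions per grid cell, 900 s of free
#' viewing), keeping the monotone trend resolvable channel by channel.
#'
#' @param seed RNG seed.
#' @param n_channels Number of channels (default 16).
#' @param visual_range Visual peak rate at the shallowest and deepest
#'   channel, Hz (default `c(400, 8)`).
#' @param motor_range Motor burst peak at the shallowest and deepest
#'   channel, Hz (default `c(8, 400)`).
#' @param ... Further arguments to [synth_config()].
#' @return A `synth_config` with 16 depth-graded channels, no calibration
#'   block, 80 RF repetitions and 900 s of free viewing.
#' @export
layered_config <- function(seed = 1, n_channels = 16,
                           visual_range = c(400, 8),
                           motor_range = c(8, 400), ...) {
  fv <- exp(seq(log(visual_range[1]), log(visual_range[2]),
                length.out = n_channels))
  fm <- exp(seq(log(motor_range[1]), log(motor_range[2]),
                length.out = n_channels))
  neurons <- lapply(seq_len(n_channels), function(k)
    neuron_spec(baseline_hz = 5, rf_peak_hz = fv[k], burst_peak_hz = fm[k],
                rf_sigma_deg = 3.5, mf_amp_deg = 14, mf_sigma_dir_deg = 45,
                mf_sigma_amp_deg = 6, burst_sd_ms = 20))
  synth_config(seed = seed, calibration_epoch_s = 0, rf_reps = 80,
               freeview_s = 900, neurons = neurons, ...)
}
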