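# Shared fixtures and independent oracles, built in code at test time.

const_trace <- function(n = 1000, rate_hz = 1000, x = 0, y = 0,
                        unit = "degrees") {
  dt <- 1000 / rate_hz
  eye_trace(seq(0, by = dt, length.out = n), rep(x, n), rep(y, n),
            unit = unit, rate_hz = rate_hz)
}

# independent moving-average oracle: naive per-sample loop with shrinking
# edge windows
ma_oracle <- function(v, w) {
  n <- length(v)
  h <- (w - 1) %/% 2
  sapply(seq_len(n), function(i) mean(v[max(1, i - h):min(n, i + h)]))
}

# independent brute-force RF oracle: per-cell loop, naive window counting
rf_brute <- function(spikes, events, grid, latency_ms, min_reps = 5) {
  rates <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  for (r in seq_len(grid$n_rows)) {
    for (cc in seq_len(grid$n_cols)) {
      ev <- events[events$row == r & events$col == cc, , drop = FALSE]
      if (nrow(ev) < min_reps) next
      tot <- 0
      for (k in seq_len(nrow(ev))) {
        a <- ev$t_onset_ms[k] + latency_ms
        tot <- tot + sum(spikes >= a & spikes < a + grid$dt_ms)
      }
      rates[r, cc] <- (tot / nrow(ev)) * (1000 / grid$dt_ms)
    }
  }
  rates
}

# independent brute-force motor-field oracle: per-saccade tally
mf_brute <- function(spikes, saccades, binning, window = c(-50, 50),
                     min_count = 3) {
  nd <- binning$n_direction_bins
  rel <- (saccades$direction - binning$direction_origin_deg) %% 360
  dir_bin <- pmin(floor(rel / binning$direction_bin_width), nd - 1)
  amp_bin <- ifelse(saccades$amplitude < binning$amplitude_edges[1], 1,
                    ifelse(saccades$amplitude < binning$amplitude_edges[2],
                           2, 3))
  rates <- matrix(NA_real_, nd, 3)
  counts <- matrix(0L, nd, 3)
  for (i in seq_len(nd)) {
    for (j in 1:3) {
      sel <- which(dir_bin == i - 1 & amp_bin == j)
      counts[i, j] <- length(sel)
      if (length(sel) < min_count) next
      tot <- 0
      for (k in sel) {
        a <- saccades$t_onset[k]
        tot <- tot + sum(spikes >= a + window[1] & spikes < a + window[2])
      }
      rates[i, j] <- tot / (length(sel) * (diff(window) / 1000))
    }
  }
  list(rates = rates, counts = counts)
}

# homogeneous Poisson spike train on [0, t_ms)
poisson_spikes <- function(rate_hz, t_ms) {
  sort(runif(rpois(1, rate_hz * t_ms / 1000), 0, t_ms))
}

# Gaze trace with n controlled minimum-jerk saccades between fixations.
# Amplitudes drawn from amp_range; directions random, reflected off the
# screen bounds. Own minimum-jerk arithmetic, independent of the package
# internals. peak_speed, when given, overrides the main-sequence duration
# so every movement has exactly that peak speed.
gen_saccade_trace <- function(n_sacc = 200, amp_range = c(2, 20),
                              rate_hz = 1000, noise_sd = 0.1,
                              fix_range_ms = c(450, 900),
                              d0 = 20, d1 = 2, peak_speed = NULL) {
  half <- c(26, 14)
  pos <- c(0, 0)
  segs <- list()
  truth <- list()
  t_cur <- 0
  for (k in seq_len(n_sacc + 1)) {
    d <- runif(1, fix_range_ms[1], fix_range_ms[2])
    segs[[length(segs) + 1]] <- c(t_cur, d, pos, 0, 0)
    t_cur <- t_cur + d
    if (k > n_sacc) break
    repeat {
      amp <- runif(1, amp_range[1], amp_range[2])
      th <- runif(1, 0, 2 * pi)
      tgt <- pos + amp * c(cos(th), sin(th))
      if (abs(tgt[1]) < half[1] && abs(tgt[2]) < half[2]) break
    }
    dur <- if (is.null(peak_speed)) d0 + d1 * amp
           else 1.875 * amp / peak_speed * 1000
    segs[[length(segs) + 1]] <- c(t_cur, dur, pos, tgt - pos)
    truth[[length(truth) + 1]] <-
      c(t_onset = t_cur, t_offset = t_cur + dur, amplitude = amp,
        direction = (th * 180 / pi) %% 360,
        peak_velocity = 1.875 * amp / (dur / 1000))
    t_cur <- t_cur + dur
    pos <- tgt
  }
  sm <- do.call(rbind, segs)
  total <- t_cur
  dt <- 1000 / rate_hz
  tg <- seq(0, total - dt, by = dt)
  idx <- findInterval(tg, sm[, 1])
  tau <- pmin(1, pmax(0, (tg - sm[idx, 1]) / sm[idx, 2]))
  s <- tau^3 * (10 - 15 * tau + 6 * tau^2)
  xg <- sm[idx, 3] + sm[idx, 5] * s + rnorm(length(tg), 0, noise_sd)
  yg <- sm[idx, 4] + sm[idx, 6] * s + rnorm(length(tg), 0, noise_sd)
  list(trace = eye_trace(tg, xg, yg, unit = "degrees", rate_hz = rate_hz),
       truth = as.data.frame(do.call(rbind, truth)))
}

# match detected saccades to ground truth by onset proximity
match_saccades <- function(detected, truth, tol_ms = 25) {
  m <- vapply(truth$t_onset, function(o) {
    if (nrow(detected) == 0) return(NA_integer_)
    d <- abs(detected$t_onset - o)
    if (min(d) <= tol_ms) which.min(d) else NA_integer_
  }, integer(1))
  hit <- !is.na(m)
  list(
    recall = mean(hit),
    precision = if (nrow(detected) > 0)
      length(unique(m[hit])) / nrow(detected) else NA_real_,
    onset_err = abs(detected$t_onset[m[hit]] - truth$t_onset[hit]),
    amp_relerr = abs(detected$amplitude[m[hit]] - truth$amplitude[hit]) /
      truth$amplitude[hit]
  )
}

# random small RF/MF instances for oracle-equivalence checks
random_rf_instance <- function() {
  grid <- stimulus_grid()
  n_ev <- sample(40:120, 1)
  events <- data.frame(
    t_onset_ms = sort(runif(n_ev, 0, 20000)),
    row = sample(6, n_ev, replace = TRUE),
    col = sample(6, n_ev, replace = TRUE),
    duration_ms = 50
  )
  list(grid = grid, events = events,
       spikes = poisson_spikes(runif(1, 5, 60), 22000),
       latency = sample(0:80, 1))
}

random_mf_instance <- function() {
  n <- sample(30:120, 1)
  onsets <- sort(runif(n, 0, 60000))
  saccades <- data.frame(
    t_onset = onsets, t_offset = onsets + 40,
    x0 = 0, y0 = 0, x1 = 1, y1 = 0,
    amplitude = runif(n, 0, 25), direction = runif(n, 0, 360)
  )
  list(saccades = saccades, spikes = poisson_spikes(runif(1, 5, 60), 61000))
}
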