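test_that("reverse correlation reproduces the hand-evaluated rate formula", {
  grid <- stimulus_grid()
  # one cell, 5 presentations, 10 spikes total in the shifted windows
  events <- data.frame(t_onset_ms = c(0, 200, 400, 600, 800),
                       row = 2, col = 3, duration_ms = 50)
  spikes <- sort(c(45, 50, 60, 89.9, 245, 250, 255, 445, 645, 845))
  map <- reverse_correlate_rf(spikes, events, grid, latency_ms = 40)
  expect_identical(map$rates[2, 3], (10 / 5) * (1000 / 50))
  expect_identical(map$rates[2, 3], 40)
  expect_true(all(is.na(map$rates[-(2 + 6 * 2)])))
  # zero spikes -> 0 Hz on defined cells
  map0 <- reverse_correlate_rf(numeric(0), events, grid, latency_ms = 40)
  expect_identical(map0$rates[2, 3], 0)
})

test_that("window edges are closed-open", {
  grid <- stimulus_grid()
  events <- data.frame(t_onset_ms = rep(0, 5), row = 1, col = 1,
                       duration_ms = 50)
  # latency 40: window [40, 90); the spike at 40 counts once per event,
  # the spike at 90 never does
  map <- reverse_correlate_rf(c(40, 90), events, grid, latency_ms = 40)
  expect_equal(map$rates[1, 1], (5 / 5) * (1000 / 50))
})

test_that("homogeneous Poisson spiking yields a flat map within
           statistical error", {
  set.seed(42)
  grid <- stimulus_grid()
  reps <- 50
  cells <- expand.grid(row = 1:6, col = 1:6)
  events <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    data.frame(t_onset_ms = ((i - 1) * reps + 0:(reps - 1)) * 50,
               row = cells$row[i], col = cells$col[i], duration_ms = 50)))
  t_end <- max(events$t_onset_ms) + 200
  spikes <- poisson_spikes(50, t_end)
  map <- reverse_correlate_rf(spikes, events, grid, latency_ms = 0)
  se <- sqrt(50 / (reps * 0.05))
  expect_true(all(abs(map$rates - 50) < 3 * se))
})

test_that("reverse correlation equals the brute-force oracle bit for bit", {
  set.seed(17)
  for (i in 1:10) {
    inst <- random_rf_instance()
    map <- reverse_correlate_rf(inst$spikes, inst$events, inst$grid,
                                latency_ms = inst$latency)
    expect_identical(map$rates,
                     rf_brute(inst$spikes, inst$events, inst$grid,
                              inst$latency))
  }
})

test_that("shifting all event and spike times leaves the map unchanged", {
  set.seed(18)
  inst <- random_rf_instance()
  m1 <- reverse_correlate_rf(inst$spikes, inst$events, inst$grid,
                             latency_ms = inst$latency)
  ev2 <- inst$events
  ev2$t_onset_ms <- ev2$t_onset_ms + 1234
  m2 <- reverse_correlate_rf(inst$spikes + 1234, ev2, inst$grid,
                             latency_ms = inst$latency)
  expect_identical(m1$rates, m2$rates)
})

test_that("input contract violations are rejected", {
  grid <- stimulus_grid()
  events <- data.frame(t_onset_ms = 0, row = 1, col = 1, duration_ms = 50)
  expect_error(reverse_correlate_rf(1:5, events[0, ], grid), "no events")
  expect_error(reverse_correlate_rf(c(5, 1), events, grid),
               "unordered spikes")
  bad <- data.frame(t_onset_ms = 0, row = 7, col = 1, duration_ms = 50)
  expect_error(reverse_correlate_rf(1:5, bad, grid), "outside the grid")
})

test_that("RF center finds hot cells and their centroid", {
  grid <- stimulus_grid()
  rates <- matrix(5, 6, 6)
  rates[2, 3] <- 100
  map <- structure(list(rates = rates, grid = grid), class = "rf_map")
  ctr <- rf_center(map)
  expect_equal(unname(ctr["x_deg"]), (3 - 3.5) * 22 / 6)
  expect_equal(unname(ctr["y_deg"]), (3.5 - 2) * 22 / 6)
  # two equal hot cells -> midway centroid
  rates2 <- matrix(5, 6, 6)
  rates2[2, 3] <- rates2[2, 4] <- 100
  map2 <- structure(list(rates = rates2, grid = grid), class = "rf_map")
  ctr2 <- rf_center(map2)
  expect_equal(unname(ctr2["x_deg"]), 0)
  # flat map carries no RF
  flat <- structure(list(rates = matrix(5, 6, 6), grid = grid),
                    class = "rf_map")
  expect_error(rf_center(flat), "no RF detected")
})

test_that("synthetic Gaussian RF center is recovered within half a cell", {
  set.seed(19)
  cfg <- synth_config(seed = 19, calibration_epoch_s = 0, rf_reps = 10,
                      freeview_s = 0)
  b <- simulate_session(cfg)
  map <- reverse_correlate_rf(b$spikes$ch01, b$rf_events, cfg$grid,
                              latency_ms = 40)
  ctr <- rf_center(map)
  truth <- cfg$neurons[[1]]$rf_center
  expect_lt(sqrt(sum((ctr - truth)^2)), 22 / 6 / 2)
})

test_that("PSTH is flat for homogeneous spiking and zero without spikes", {
  set.seed(20)
  aligns <- seq(1000, 480000, by = 960)
  spikes <- poisson_spikes(30, 500000)
  p <- psth(spikes, aligns, window = c(-100, 100), bin_ms = 20)
  se <- sqrt(30 / (length(aligns) * 0.02))
  expect_true(all(abs(p$rate - 30) < 4 * se))
  p0 <- psth(numeric(0), aligns, window = c(-100, 100), bin_ms = 20)
  expect_true(all(p0$rate == 0))
  expect_error(psth(spikes, numeric(0)), "empty align_times")
})

test_that("per-cell PSTH rate over the response window reproduces the RF
           map", {
  set.seed(22)
  inst <- random_rf_instance()
  map <- reverse_correlate_rf(inst$spikes, inst$events, inst$grid,
                              latency_ms = inst$latency, min_reps = 1)
  for (cell in list(c(1, 1), c(3, 4), c(6, 6))) {
    ev <- inst$events[inst$events$row == cell[1] &
                        inst$events$col == cell[2], ]
    if (nrow(ev) == 0) next
    p <- psth(inst$spikes, ev$t_onset_ms,
              window = c(inst$latency, inst$latency + 50), bin_ms = 50)
    expect_equal(p$rate, map$rates[cell[1], cell[2]])
  }
})

test_that("embedded response latency is recovered by the grid search", {
  set.seed(23)
  for (lat in c(40, 0)) {
    neurons <- list(neuron_spec(latency_ms = lat, rf_peak_hz = 150))
    cfg <- synth_config(seed = 23 + lat, calibration_epoch_s = 0,
                        rf_reps = 10, freeview_s = 0, neurons = neurons)
    b <- simulate_session(cfg)
    est <- estimate_latency(b$spikes$ch01, b$rf_events, cfg$grid)
    expect_false(est$flagged)
    expect_lte(abs(est$latency_ms - lat), 5)
  }
})

test_that("stimulus-independent spiking flags the latency estimate", {
  set.seed(24)
  inst <- random_rf_instance()
  est <- estimate_latency(inst$spikes, inst$events, inst$grid)
  expect_true(est$flagged)
  expect_equal(est$latency_ms, 40)
})
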