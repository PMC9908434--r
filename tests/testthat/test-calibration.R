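make_fix <- function(t_start, t_end, cx, cy) {
  data.frame(t_start = t_start, t_end = t_end, duration = t_end - t_start,
             cx = cx, cy = cy, label = NA_integer_)
}

test_that("fixations are labeled only when fully inside an epoch", {
  sched <- calibration_schedule(epoch_s = 10)
  fx <- make_fix(c(21000, 9500, 3000), c(22000, 10500, 3600),
                 c(0, 0, 0), c(0, 0, 0))
  lab <- label_fixations(fx, sched)
  expect_equal(lab$label, c(3L, NA_integer_, 1L))
  expect_error(label_fixations(fx, sched[0, ]), "empty schedule")
})

test_that("gaussian fit recovers a symmetric cluster center", {
  vals <- rep(c(4.9, 5.0, 5.1), each = 30)
  fit <- fit_gaussian(vals)
  expect_lt(abs(fit$b - 5.0), 0.05)
  expect_gt(fit$c, 0)
})

test_that("gaussian fit center agrees with the sample-mean oracle", {
  set.seed(10)
  vals <- rnorm(1000, mean = 2.0, sd = 0.5)
  fit <- fit_gaussian(vals)
  expect_lt(abs(fit$b - 2.0), 3 * 0.5 / sqrt(1000))
  expect_equal(fit$c / sqrt(2), 0.5, tolerance = 0.15)
})

test_that("gaussian fit flags bimodal input through its residual", {
  set.seed(11)
  a <- rnorm(200, 0, 0.4)
  b <- rnorm(200, 10, 0.4)
  both <- fit_gaussian(c(a, b))
  expect_gt(both$rmse, fit_gaussian(a)$rmse)
  expect_gt(both$rmse, fit_gaussian(b)$rmse)
})

test_that("gaussian fit rejects undersized clusters", {
  expect_error(fit_gaussian(c(1, 2, 3)), "insufficient fixations")
})

test_that("raw centers already at stimulus locations give identity
           calibration", {
  set.seed(15)
  sched <- calibration_schedule(epoch_s = 10)
  fx <- do.call(rbind, lapply(seq_len(nrow(sched)), function(i) {
    jit <- rnorm(30, 0, 0.2)
    jit <- c(jit, -jit)  # exactly symmetric scatter about the stimulus
    make_fix(rep(sched$t_start_ms[i] + 100, 60),
             rep(sched$t_start_ms[i] + 700, 60),
             sched$x_deg[i] + jit, sched$y_deg[i] + rev(jit))
  }))
  lab <- label_fixations(fx, sched)
  res <- estimate_calibration(lab, sched)
  expect_equal(res$cal_x$gain, 1, tolerance = 0.02)
  expect_equal(res$cal_y$gain, 1, tolerance = 0.02)
  expect_equal(res$cal_x$offset, 0, tolerance = 0.05)
  expect_equal(res$cal_y$offset, 0, tolerance = 0.05)
  # the default five locations span x centers at -7, 0, 7 degrees
  expect_setequal(round(sort(unique(res$centers$x_deg))), c(-7, 0, 7))
})

test_that("known gain and offset are recovered from noisy volt clusters", {
  set.seed(12)
  gain <- c(5, 4)
  offset <- c(2, -1)
  sched <- calibration_schedule(epoch_s = 10)
  fx <- do.call(rbind, lapply(seq_len(nrow(sched)), function(i) {
    n <- 200
    raw_x <- (sched$x_deg[i] - offset[1]) / gain[1] + rnorm(n, 0, 0.3)
    raw_y <- (sched$y_deg[i] - offset[2]) / gain[2] + rnorm(n, 0, 0.3)
    make_fix(rep(sched$t_start_ms[i] + 100, n),
             rep(sched$t_start_ms[i] + 700, n), raw_x, raw_y)
  }))
  lab <- label_fixations(fx, sched)
  res <- estimate_calibration(lab, sched)
  expect_equal(res$cal_x$gain, gain[1], tolerance = 0.02)
  expect_equal(res$cal_y$gain, gain[2], tolerance = 0.02)
  expect_lt(abs(res$cal_x$offset - offset[1]), 0.2)
  expect_lt(abs(res$cal_y$offset - offset[2]), 0.2)
})

test_that("a schedule with collinear stimuli is rejected as degenerate", {
  sched <- calibration_schedule(matrix(c(-7, 0, 0, 0, 7, 0), ncol = 2,
                                       byrow = TRUE), epoch_s = 10)
  fx <- do.call(rbind, lapply(1:3, function(i)
    make_fix(rep(sched$t_start_ms[i] + 100, 10),
             rep(sched$t_start_ms[i] + 700, 10),
             rnorm(10, i), rnorm(10, 0))))
  lab <- label_fixations(fx, sched)
  expect_error(estimate_calibration(lab, sched), "degenerate schedule")
})

test_that("calibration is an invertible affine map with a unit tag", {
  res <- list(cal_x = list(gain = 5, offset = 2),
              cal_y = list(gain = 4, offset = -1))
  tr <- const_trace(100, 120, x = 0.5, y = -0.2, unit = "volts")
  cal <- apply_calibration(tr, res)
  expect_equal(cal$unit, "degrees")
  expect_equal(cal$x, rep(5 * 0.5 + 2, 100))
  expect_error(apply_calibration(cal, res), "already calibrated")
  back <- invert_calibration(cal, res)
  expect_equal(back$x, tr$x, tolerance = 1e-12)
  expect_equal(back$y, tr$y, tolerance = 1e-12)
  # identity calibration only flips the tag
  id <- list(cal_x = list(gain = 1, offset = 0),
             cal_y = list(gain = 1, offset = 0))
  expect_equal(apply_calibration(tr, id)$x, tr$x)
})

test_that("estimation is scale-equivariant in the raw units", {
  set.seed(13)
  sched <- calibration_schedule(epoch_s = 10)
  base <- do.call(rbind, lapply(seq_len(nrow(sched)), function(i) {
    n <- 30
    make_fix(rep(sched$t_start_ms[i] + 100, n),
             rep(sched$t_start_ms[i] + 700, n),
             sched$x_deg[i] / 5 + rnorm(n, 0, 0.2),
             sched$y_deg[i] / 5 + rnorm(n, 0, 0.2))
  }))
  lab <- label_fixations(base, sched)
  res1 <- estimate_calibration(lab, sched)
  k <- 3.7
  scaled <- lab
  scaled$cx <- scaled$cx * k
  scaled$cy <- scaled$cy * k
  res2 <- estimate_calibration(scaled, sched)
  expect_equal(res2$cal_x$gain, res1$cal_x$gain / k, tolerance = 1e-6)
  expect_equal(res2$cal_y$gain, res1$cal_y$gain / k, tolerance = 1e-6)
  # calibrated cluster centers unchanged
  expect_equal(res2$centers$bx_cal, res1$centers$bx_cal, tolerance = 1e-6)
  expect_equal(res2$centers$by_cal, res1$centers$by_cal, tolerance = 1e-6)
})

test_that("offset recalibration shifts offsets by the fixation-point
           displacement", {
  res <- list(cal_x = list(gain = 5, offset = 2),
              cal_y = list(gain = 4, offset = -1))
  # centroid displaced (+1.0, -0.5) from the fixation point at (0, 0)
  fx <- make_fix(1:10 * 1000, 1:10 * 1000 + 600,
                 rnorm(10, 1, 0.01), rnorm(10, -0.5, 0.01))
  out <- offset_recalibrate(fx, c(0, 0), res)
  expect_equal(out$cal_x$gain, 5)
  expect_equal(out$cal_x$offset, 2 - 1, tolerance = 0.02)
  expect_equal(out$cal_y$offset, -1 + 0.5, tolerance = 0.02)
  # centroid already at the fixation point: unchanged
  fx0 <- make_fix(1:10 * 1000, 1:10 * 1000 + 600, rep(3, 10), rep(-2, 10))
  out0 <- offset_recalibrate(fx0, c(3, -2), res)
  expect_equal(out0$cal_x$offset, 2)
  expect_equal(out0$cal_y$offset, -1)
  expect_error(offset_recalibrate(fx0[0, ], c(0, 0), res), "no fixations")
})

test_that("residual report flags absent epochs instead of zeroing them", {
  set.seed(14)
  sched <- calibration_schedule(epoch_s = 10)
  fx <- do.call(rbind, lapply(c(1, 2, 3, 5), function(i) {  # epoch 4 missing
    n <- 30
    make_fix(rep(sched$t_start_ms[i] + 100, n),
             rep(sched$t_start_ms[i] + 700, n),
             sched$x_deg[i] / 5 + rnorm(n, 0, 0.1),
             sched$y_deg[i] / 5 + rnorm(n, 0, 0.1))
  }))
  lab <- label_fixations(fx, sched)
  res <- estimate_calibration(lab, sched)
  rep <- residual_report(res)
  expect_true(rep$per_epoch$absent[4])
  expect_true(is.na(rep$per_epoch$residual_deg[4]))
  expect_false(any(rep$per_epoch$absent[-4]))
  expect_true(all(rep$per_epoch$residual_deg[-4] < 0.5))
})
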