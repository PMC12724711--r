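test_that("dark-count subtraction and summation reproduce the arithmetic case", {
  t <- seq(0, 2, by = 1 / 60)
  dark <- (t * 60) %% 15 < 1
  a <- biolum_trace(t, ifelse(dark, 5, 100), dark = dark)
  b <- biolum_trace(t, ifelse(dark, 3, 80), dark = dark)
  out <- subtract_dark_and_sum(a, b)
  expect_false(any(out$time_hours %in% t[dark]))
  expect_true(all(abs(out$value - 172) < 1e-9))
})

test_that("dark-only sensors correct to approximately zero", {
  t <- seq(0, 2, by = 1 / 60)
  dark <- (t * 60) %% 15 < 1
  withr::with_seed(4, {
    a <- biolum_trace(t, rpois(length(t), 6), dark = dark)
    b <- biolum_trace(t, rpois(length(t), 6), dark = dark)
  })
  out <- subtract_dark_and_sum(a, b)
  # local dark estimates carry counting noise of ~sqrt(6)/sqrt(4) per window
  expect_lt(abs(mean(out$value)), 2.5)
})

test_that("the simulated dark offset is removed within counting error", {
  sc <- sim_scenario(seed = 5, duration = 48, sampling_interval = 1,
                     baseline0 = 400, noise = "poisson",
                     units = oscillator_truth("u", amplitude_rel = 0),
                     dark_interval = 15, dark_duration = 1, dark_rate = 12)
  sim <- simulate_pmt_trace(sc)
  out <- subtract_dark_and_sum(sim$sensor_a, sim$sensor_b)
  # true signal is the constant baseline 400
  expect_lt(abs(mean(out$value) - 400), 3 * sqrt(400 / nrow(out)) + 1)
  expect_error(subtract_dark_and_sum(sim$sensor_a,
                                     biolum_trace(0:3, rep(1, 4))),
               "time grid")
})

test_that("24-h running mean detrending has its stated fixed points", {
  t <- seq(0, 120, by = 1 / 6)
  cosine <- cos(2 * pi * (t - 13) / 24)
  det <- running_mean_detrend(biolum_trace(t, cosine))
  inner <- det$valid
  expect_lt(max(abs(det$value[inner] - cosine[inner])), 1e-6)
  # linear ramp is annihilated
  det2 <- running_mean_detrend(biolum_trace(t, 5 + 3 * t))
  expect_lt(max(abs(det2$value[det2$valid])), 1e-9)
  # edge samples are invalidated, not padded
  expect_false(any(det$valid[t < 12]))
  expect_false(any(det$valid[t > max(t) - 12]))
  expect_true(all(is.na(det$value[!det$valid])))
  expect_error(running_mean_detrend(biolum_trace(0:10, rnorm(11))), "span")
})

test_that("running-mean detrending commutes with additive constants and tames growth", {
  t <- seq(0, 120, by = 1 / 6)
  x <- cos(2 * pi * t / 24) + 0.1 * rnorm(length(t))
  d1 <- running_mean_detrend(biolum_trace(t, x))
  d2 <- running_mean_detrend(biolum_trace(t, x + 1000))
  expect_equal(d1$value, d2$value, tolerance = 1e-9)
  # exponential growth over a full gestation-like record: the 24-h window
  # mean leaves the second-order residual -(sinh(12g)/(12g) - 1) exp(g t),
  # whose slope is that same fraction of the input slope (the analytic
  # ceiling on trend suppression for this window and growth rate)
  g <- log(100) / 216
  leftover <- sinh(12 * g) / (12 * g) - 1
  tg <- seq(0, 216, by = 0.25)
  ye <- exp(g * tg)
  dete <- running_mean_detrend(biolum_trace(tg, ye))
  keep <- dete$valid
  expect_equal(dete$value[keep], -leftover * ye[keep], tolerance = 0.02)
  s_in <- abs(coef(lm(ye ~ tg))[2])
  s_out <- abs(coef(lm(dete$value[keep] ~ tg[keep]))[2])
  expect_equal(unname(s_out / s_in), leftover, tolerance = 0.15)
  # with circadian modulation on top, the trend slope still collapses
  y <- ye * (1 + 0.3 * cos(2 * pi * (tg - 13) / 24))
  det <- running_mean_detrend(biolum_trace(tg, y))
  s_in2 <- abs(coef(lm(y ~ tg))[2])
  s_out2 <- abs(coef(lm(det$value[det$valid] ~ tg[det$valid]))[2])
  expect_lt(s_out2, s_in2 / 50)
})

test_that("sinc detrend/smooth contracts noise, preserves circadian amplitude, kills constants", {
  t <- seq(0, 120, by = 1 / 6)
  withr::with_seed(6, x <- rnorm(length(t)))
  sm <- sinc_detrend_smooth(biolum_trace(t, x), 48, 4)
  expect_lt(var(sm$value), var(x))
  cosine <- cos(2 * pi * (t - 13) / 24)
  out <- sinc_detrend_smooth(biolum_trace(t, 100 + cosine), 48, 4)
  mid <- t > 24 & t < 96
  amp <- (max(out$value[mid]) - min(out$value[mid])) / 2
  expect_equal(amp, 1, tolerance = 0.05)
  cst <- sinc_detrend_smooth(biolum_trace(t, rep(7, length(t))), 48, 4)
  expect_lt(max(abs(cst$value)), 1e-9)
  expect_error(sinc_detrend_smooth(biolum_trace(t, x), 4, 48), "cutoff")
})

test_that("adjacent-frame minimization removes every injected spike", {
  sim <- make_dam(3)
  sp <- sim$truth$spikes
  expect_gt(nrow(sp), 3)
  clean <- adjacent_frame_minimize(sim$stack)
  raw <- sim$stack$frames
  for (i in seq_len(nrow(sp))) {
    k <- sp$frame[i]
    neighbours <- raw[sp$row[i], sp$col[i],
                      c(max(1, k - 1), min(dim(raw)[3], k + 1))]
    expect_lte(clean$frames[sp$row[i], sp$col[i], k], max(neighbours))
  }
  spiked <- raw[cbind(sp$row, sp$col, sp$frame)]
  cleaned <- clean$frames[cbind(sp$row, sp$col, sp$frame)]
  expect_true(all(cleaned < spiked - 0.5 * sp$added))
})

test_that("minimization keeps the earlier frame on monotone signal and bounds change on smooth stacks", {
  f <- array(rep(1:5, each = 4), c(2, 2, 5))   # monotone increasing
  st <- image_stack(f, 1:5)
  out <- adjacent_frame_minimize(st)
  expect_equal(out$frames[, , 1:4], f[, , 1:4])
  expect_equal(out$frames[, , 5], f[, , 4])    # last frame paired backward
  expect_error(adjacent_frame_minimize(image_stack(f[, , 1, drop = FALSE], 1)),
               ">= 2")
  # spike-free smooth stack: change bounded by inter-frame difference
  t <- seq(0, 48, by = 1)
  sm <- array(0, c(3, 3, length(t)))
  for (k in seq_along(t)) sm[, , k] <- 100 + 10 * sin(2 * pi * t[k] / 24)
  stm <- adjacent_frame_minimize(image_stack(sm, t))
  dmax <- max(abs(sm[, , -1] - sm[, , -length(t)]))
  expect_lte(max(abs(stm$frames - sm)), dmax)
})

test_that("frame averaging counts, averages, and leaves constants alone", {
  f <- array(rnorm(4 * 4 * 10), c(4, 4, 10))
  st <- image_stack(f, seq(0.5, 5, by = 0.5))
  out <- frame_average(st, 2)
  expect_equal(dim(out$frames)[3], 5)
  expect_equal(out$frames[, , 1], (f[, , 1] + f[, , 2]) / 2)
  expect_equal(out$timestamps[1], 0.75)
  cst <- frame_average(image_stack(array(3, c(2, 2, 6)), 1:6), 3)
  expect_true(all(cst$frames == 3))
  ab <- array(rep(c(2, 8), 5), c(1, 1, 10))
  expect_true(all(frame_average(image_stack(ab, 1:10), 2)$frames == 5))
  expect_identical(frame_average(st, 1), st)
  expect_error(frame_average(st, 0), "n must")
})

test_that("ROI flux subtracts background exactly", {
  roi <- matrix(FALSE, 6, 6); roi[2:3, 2:6] <- TRUE
  bg <- matrix(FALSE, 6, 6); bg[6, ] <- TRUE
  f <- array(4, c(6, 6, 2))
  st <- image_stack(f, c(0, 1), roi_mask = roi, background_mask = bg)
  expect_true(all(roi_flux(st)$value == 0))
  f2 <- array(2, c(6, 6, 1)); f2[2:3, 2:6, 1] <- 7
  st2 <- image_stack(f2, 0, roi_mask = roi, background_mask = bg)
  expect_equal(roi_flux(st2)$value, sum(roi) * (7 - 2))
  expect_error(roi_flux(image_stack(f, c(0, 1), roi_mask = roi)), "background")
})

test_that("ROI flux tracks the summed simulated unit signal", {
  geom <- list(dim = c(12, 12),
               regions = tibble::tibble(unit_id = "u", row_min = 4, row_max = 8,
                                        col_min = 4, col_max = 8))
  sc <- sim_scenario(seed = 8, duration = 72, sampling_interval = 60,
                     baseline0 = 200, noise = "none",
                     units = oscillator_truth("u", period = 24, peak_time = 13,
                                              amplitude_rel = 0.3))
  sim <- simulate_image_stack(sc, geom)
  fl <- roi_flux(sim$stack)
  npx <- sum(sim$stack$roi_mask)
  truth <- npx * 200 * (1 + 0.3 * cos(2 * pi * (fl$time_hours - 13) / 24))
  expect_equal(fl$value, truth, tolerance = 1e-6)
})

test_that("pixel extraction is the identity at sigma 0 and spreads mass like the kernel", {
  f <- array(rnorm(8 * 8 * 3, 100, 5), c(8, 8, 3))
  roi <- matrix(TRUE, 8, 8)
  st <- image_stack(f, 1:3, roi_mask = roi)
  px <- extract_pixel_series(st, gaussian_sigma = 0)
  one <- px[px$row == 3 & px$col == 5, ]
  expect_equal(one$value, f[3, 5, ])
  # single bright pixel: centre retains the kernel's central weight 1/(2 pi sigma^2)
  f2 <- array(0, c(21, 21, 1)); f2[11, 11, 1] <- 1
  st2 <- image_stack(f2, 0, roi_mask = matrix(TRUE, 21, 21))
  px2 <- extract_pixel_series(st2, gaussian_sigma = 1)
  centre <- px2$value[px2$row == 11 & px2$col == 11]
  expect_equal(centre, 1 / (2 * pi), tolerance = 0.02)
  expect_error(extract_pixel_series(st, gaussian_sigma = -1), "sigma")
})

test_that("pixels of a dispersion-free unit are proportional time series", {
  geom <- list(dim = c(10, 10),
               regions = tibble::tibble(unit_id = "u", row_min = 3, row_max = 6,
                                        col_min = 3, col_max = 6))
  sc <- sim_scenario(seed = 9, duration = 48, sampling_interval = 60,
                     baseline0 = 100, noise = "none",
                     units = oscillator_truth("u", amplitude_rel = 0.5))
  sim <- simulate_image_stack(sc, geom)
  px <- extract_pixel_series(sim$stack, gaussian_sigma = 0)
  wide <- tidyr::pivot_wider(px[, c("pixel", "time_hours", "value")],
                             names_from = "pixel", values_from = "value")
  m <- as.matrix(wide[, -1]) - 5  # remove the background plane
  cors <- cor(m)
  expect_true(all(cors > 1 - 1e-9))
})
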