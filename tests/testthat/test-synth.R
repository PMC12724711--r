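test_that("a PMT trace with no modulation is the exponential baseline plus dark offset", {
  sc <- sim_scenario(seed = 1, duration = 48, sampling_interval = 1,
                     baseline0 = 100, growth_rate = 0.01, noise = "none",
                     units = oscillator_truth("u", amplitude_rel = 0),
                     dark_interval = 15, dark_duration = 1, dark_rate = 8)
  sim <- simulate_pmt_trace(sc)
  tr <- sim$trace
  lit <- !tr$dark
  expect_equal(tr$value[lit],
               100 * exp(0.01 * tr$time_hours[lit]) + 2 * 8,
               tolerance = 1e-12)
  expect_true(all(tr$value[tr$dark] == 2 * 8))
})

test_that("detrended noiseless PMT signal peaks once per day at the stated ZT after onset", {
  sc <- sim_scenario(seed = 1, duration = 144, sampling_interval = 10,
                     baseline0 = 500, growth_rate = 0, noise = "none",
                     units = oscillator_truth("u", period = 24, peak_time = 13,
                                              amplitude_rel = 0.5,
                                              onset_time = 24))
  sim <- simulate_pmt_trace(sc)
  det <- running_mean_detrend(sim$trace)
  pk <- daily_peak_times(det)
  post <- pk[pk$time_hours > 24 + 24, ]   # clear of the onset ramp
  expect_true(nrow(post) >= 3)
  expect_equal(nrow(post), length(unique(post$day)))  # one max per day
  expect_true(all(circ_abs_diff(post$time_zt, 13) <= 10 / 60 + 1e-8))
})

test_that("the default gestational growth rate gives a 100-fold baseline rise", {
  g <- log(100) / 216
  sc <- sim_scenario(seed = 1, duration = 216, sampling_interval = 60,
                     baseline0 = 10, growth_rate = g, noise = "none",
                     dark_rate = 0,
                     units = oscillator_truth("u", amplitude_rel = 0))
  sim <- simulate_pmt_trace(sc)
  ratio <- sim$trace$value[nrow(sim$trace)] / sim$trace$value[1]
  expect_equal(ratio, 100, tolerance = 0.01)
})

test_that("zero-dispersion image units share one phase and give Kuramoto r = 1", {
  geom <- list(dim = c(10, 10),
               regions = tibble::tibble(unit_id = "u", row_min = 3, row_max = 7,
                                        col_min = 3, col_max = 7))
  sc <- sim_scenario(seed = 2, duration = 96, sampling_interval = 60,
                     baseline0 = 300, noise = "none",
                     units = oscillator_truth("u", period = 24, peak_time = 13,
                                              amplitude_rel = 0.4),
                     phase_dispersion_start = 0, phase_dispersion_end = 0,
                     spike_rate = 0)
  sim <- simulate_image_stack(sc, geom)
  expect_true(all(sim$truth$pixels$delta0 == 0))
  px <- extract_pixel_series(background_subtract(sim$stack), gaussian_sigma = 0)
  ph <- pixel_wavelet_phase(px, resample_dt = 1)
  sy <- sync_timecourse(ph, smooth_hours = 0, power_gate = FALSE)
  expect_true(all(sy$r > 1 - 1e-6))
})

test_that("two units 6 h apart reproduce the closed-form two-point circular SD", {
  geom <- list(dim = c(12, 12),
               regions = tibble::tibble(unit_id = c("a", "b"),
                                        row_min = c(3, 3), row_max = c(5, 5),
                                        col_min = c(3, 8), col_max = c(5, 10)))
  sc <- sim_scenario(seed = 3, duration = 96, sampling_interval = 60,
                     baseline0 = 300, noise = "none",
                     units = oscillator_truth(c("a", "b"), period = 24,
                                              peak_time = c(10, 16),
                                              amplitude_rel = 0.4),
                     phase_dispersion_start = 0)
  sim <- simulate_image_stack(sc, geom)
  peak_by_unit <- c(a = 10, b = 16)
  pk <- peak_by_unit[sim$truth$pixels$unit_id]
  th <- 2 * pi * pk / 24
  R <- Mod(mean(exp(1i * th)))
  # closed form for two equal atoms +-3 h from the mean direction
  R_expected <- cos(2 * pi * 3 / 24)
  expect_equal(R, R_expected, tolerance = 1e-12)
  sd_hours <- sqrt(-2 * log(R)) * 24 / (2 * pi)
  expect_equal(sd_hours, sqrt(-2 * log(R_expected)) * 24 / (2 * pi),
               tolerance = 1e-9)
})

test_that("injected cosmic-ray spikes occupy exactly one frame each", {
  sim <- make_dam(1)
  sp <- sim$truth$spikes
  expect_gt(nrow(sp), 0)
  expect_false(any(duplicated(sp[, c("frame", "row", "col")])))
  expect_true(all(sp$added >= 20))
})

test_that("overlapping unit regions are rejected", {
  geom <- list(dim = c(10, 10),
               regions = tibble::tibble(unit_id = c("a", "b"),
                                        row_min = c(2, 4), row_max = c(6, 8),
                                        col_min = c(2, 4), col_max = c(6, 8)))
  sc <- sim_scenario(units = oscillator_truth(c("a", "b")))
  expect_error(simulate_image_stack(sc, geom), "overlap")
})

test_that("undamped noiseless explants have peak-to-trough 2A and peaks at the stated ZT", {
  tr <- make_explant(damping = 0, noise = "none", amp = 0.4, baseline0 = 500)
  A <- 0.4 * 500
  for (start in c(12, 36, 60)) {
    win <- tr[tr$time_hours >= start & tr$time_hours <= start + 24, ]
    expect_equal(max(win$value) - min(win$value), 2 * A, tolerance = 1e-3)
  }
  pk <- daily_peak_times(tr)
  expect_true(all(circ_abs_diff(pk$time_zt, 13) < 0.2))
})

test_that("the damped-envelope decay matches its analytic value", {
  tr <- make_explant(damping = 0.01, noise = "none", amp = 0.4,
                     baseline0 = 500, peak = 13)
  # cycle-k amplitude: peak-to-trough within cycle k
  cyc_amp <- function(k) {
    win <- tr[tr$time_hours >= (k - 1) * 24 & tr$time_hours <= k * 24, ]
    max(win$value) - min(win$value)
  }
  expect_equal(cyc_amp(4) / cyc_amp(1), exp(-0.01 * 72), tolerance = 0.01)
})

test_that("simulated peak times follow the von Mises model", {
  # huge concentration collapses onto the mean
  pk <- simulate_peak_times(20, mean_peak = 13, concentration = 1e6, seed = 1)
  expect_true(all(circ_abs_diff(pk$time_zt, 13) < 0.1))
  # kappa = 0: uniform, R ~ sqrt(pi)/(2 sqrt(n))
  pk0 <- simulate_peak_times(10000, concentration = 0, seed = 2)
  expect_lt(rayleigh_stat(pk0)$R, 0.03)
  # kappa = 2: circular mean near the target over several seeds
  for (s in 1:3) {
    pk2 <- simulate_peak_times(1000, mean_peak = 13, concentration = 2, seed = s)
    expect_lt(circ_abs_diff(rayleigh_stat(pk2)$mean_direction, 13), 0.25)
  }
})

test_that("generators validate their scenarios and are reproducible", {
  expect_error(sim_scenario(duration = -1), "duration")
  expect_error(sim_scenario(sampling_interval = 0), "sampling_interval")
  expect_error(sim_scenario(units = oscillator_truth("u")[0, ]), "unit")
  expect_error(oscillator_truth("u", period = 50), "period")
  expect_error(oscillator_truth("u", amplitude_rel = -1), "amplitude")

  sc <- sim_scenario(seed = 9, duration = 24, sampling_interval = 10,
                     noise = "poisson")
  a <- simulate_pmt_trace(sc); b <- simulate_pmt_trace(sc)
  expect_identical(a$trace$value, b$trace$value)  # seeded: bit-reproducible
  expect_true(all(is.finite(a$trace$value)) && all(a$trace$value >= 0))
  expect_true(all(diff(a$trace$time_hours) > 0))

  sim <- make_dam(2); sim2 <- make_dam(2)
  expect_identical(sim$stack$frames, sim2$stack$frames)
  expect_true(all(sim$stack$frames >= 0))
})
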