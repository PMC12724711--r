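test_that("Lomb-Scargle nails a noiseless circadian cosine", {
  t <- seq(0, 120, by = 1 / 6)
  tr <- biolum_trace(t, cos(2 * pi * (t - 13) / 24))
  res <- lomb_scargle_test(tr)
  expect_equal(res$period, 24, tolerance = 0.2 / 24)
  expect_lt(res$p_value, 1e-6)
  expect_error(lomb_scargle_test(biolum_trace(0:20, rnorm(21))), "span")
})

test_that("Lomb-Scargle handles the mixed gestational sampling schedule", {
  sched <- gestation_schedule()
  withr::with_seed(10, {
    tr <- biolum_trace(sched, cos(2 * pi * (sched - 13) / 24) +
                         0.2 * rnorm(length(sched)))
  })
  res <- lomb_scargle_test(tr)
  expect_true(res$period >= 18 && res$period <= 30)
  expect_lt(res$p_value, 0.05)
})

test_that("Lomb-Scargle type-I error is controlled on white noise", {
  t <- seq(0, 120, by = 1 / 6)
  withr::with_seed(11, {
    p <- replicate(500, {
      lomb_scargle_test(tibble::tibble(time_hours = t,
                                       value = rnorm(length(t))))$p_value
    })
  })
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("the rank-template test is perfectly concordant with its matched cosine", {
  t <- seq(0, 120, by = 1)
  tr <- biolum_trace(t, cos(2 * pi * t / 24))
  res <- jtk_test(tr, template_step = 2)
  expect_equal(res$stat, 1, tolerance = 1e-9)
  expect_equal(res$period, 24)
  expect_equal(res$lag, 0)
  expect_lt(res$p_value, 1e-10)
})

test_that("degenerate inputs to the rank-template test are non-rhythmic", {
  t <- seq(0, 120, by = 1)
  expect_equal(jtk_test(biolum_trace(t, rep(5, length(t))))$p_value, 1)
  # a detrended ramp is flat (zero up to rounding): nothing left for any
  # template to concord with
  det <- running_mean_detrend(biolum_trace(seq(0, 120, by = 1 / 6),
                                           1 + 2 * seq(0, 120, by = 1 / 6)))
  expect_lt(max(abs(det$value[det$valid])), 1e-9)
  det$value[det$valid] <- round(det$value[det$valid], 6)
  expect_equal(jtk_test(det)$p_value, 1)
  expect_error(jtk_test(biolum_trace(0:6, rnorm(7))), "bins")
})

test_that("meta combination has its closed-form identities", {
  one <- tibble::tibble(method = "x", period = 23.5, p_value = 0.01)
  expect_equal(meta_combine(one)$p_value, 0.01)
  expect_equal(meta_combine(one)$period, 23.5)
  two <- tibble::tibble(method = c("a", "b"), period = c(24, 24),
                        p_value = c(0.5, 0.5))
  got <- meta_combine(two)
  expect_equal(got$p_value,
               pchisq(-2 * (log(0.5) + log(0.5)), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(got$p_value, 0.5966, tolerance = 1e-3)
  expect_equal(got$period, 24)
  expect_error(meta_combine(two[0, ]), "no member")
})

test_that("the circadian classification rule is exact and monotone in p", {
  expect_true(classify_circadian(24, 0.01))
  expect_false(classify_circadian(16, 0.001))
  expect_false(classify_circadian(24, 0.05))   # strict inequality
  expect_true(classify_circadian(18, 0.049))
  expect_true(classify_circadian(30, 0.049))
  expect_false(classify_circadian(30.01, 0.001))
  # monotone: lowering p never flips TRUE -> FALSE at fixed period
  for (T in c(18, 24, 30)) {
    ps <- c(0.049, 0.01, 1e-4, 1e-8)
    cls <- vapply(ps, function(p) classify_circadian(T, p), logical(1))
    expect_true(all(diff(as.integer(cls)) >= 0))
  }
})

test_that("the three period estimators agree within an hour on clean cosines", {
  t <- seq(0, 150, by = 1 / 6)
  for (T in c(18, 21, 24, 27, 30)) {
    tr <- biolum_trace(t, cos(2 * pi * t / T))
    pls <- lomb_scargle_test(tr)$period
    pjtk <- jtk_test(tr)$period
    ph <- harmonic_test(tr)$period
    fit <- fit_damped_cosine(tr, fit_window = c(24, 144))
    expect_lt(abs(pls - T), 1)
    expect_lt(abs(pjtk - T), 1.01)   # 2-h template grid
    expect_lt(abs(ph - T), 1)
    expect_lt(abs(fit$period - T), 1)
  }
})

test_that("the meta test detects simulated rhythms and stays quiet on constants", {
  tr <- make_explant(seed = 21)
  det <- running_mean_detrend(tr)
  res <- meta_rhythm_test(det)
  expect_true(res$is_circadian)
  expect_equal(res$period, 24, tolerance = 0.05)
  flat <- meta_rhythm_test(biolum_trace(seq(0, 120, 1 / 6),
                                        rep(3, 721)))
  expect_false(flat$is_circadian)
  expect_equal(flat$p_value, 1)
})
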