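drop_invalid <- function(trace) {
  if ("valid" %in% names(trace)) trace <- trace[trace$valid & is.finite(trace$value), ]
  trace
}

#' Lomb-Scargle rhythm test
#'
#' Normalized Lomb-Scargle periodogram over a circadian period band,
#' suited to uneven sampling (including the mixed 12-h/4-h gestational
#' schedule). The p-value is the extreme-value false-alarm probability of
#' the peak normalized power over the scanned band (Baluev-style aliasing-
#' free bound on top of the finite-sample beta tail of a single
#' frequency), which controls the band-maximum multiplicity far better
#' than a naive independent-frequency count.
#'
#' @param trace a (detrended) trace spanning at least two cycles of the
#'   shortest period sought.
#' @param period_range c(min, max) period in hours.
#' @param oversample frequency oversampling factor of the scan grid.
#' @return one-row tibble: `method`, `period`, `p_value`, `stat` (peak
#'   normalized power).
#' @export
lomb_scargle_test <- function(trace, period_range = c(18, 30), oversample = 8) {
  trace <- drop_invalid(trace)
  t <- trace$time_hours; x <- trace$value
  span <- diff(range(t))
  if (span < 2 * period_range[1]) {
    stopf("record spans %.1f h; >= %.0f h needed for periods down to %g h",
          span, 2 * period_range[1], period_range[1])
  }
  x <- x - mean(x)
  s2 <- stats::var(x)
  if (s2 == 0) {
    return(tibble::tibble(method = "lomb_scargle", period = NA_real_,
                          p_value = 1, stat = 0))
  }
  f1 <- 1 / period_range[2]; f2 <- 1 / period_range[1]
  df <- 1 / (oversample * span)
  freqs <- seq(f1, f2, by = df)
  power <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2)) / (2 * s2)
  }, numeric(1))
  k <- which.max(power)
  # parabolic refinement of the peak frequency (the scan grid is coarse
  # relative to printed period precision at long periods)
  f_best <- freqs[k]
  if (k > 1 && k < length(freqs)) {
    y1 <- power[k - 1]; y2 <- power[k]; y3 <- power[k + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) f_best <- freqs[k] + 0.5 * (y1 - y3) / den * df
  }
  z <- power[k]
  n <- length(t)
  # single-frequency tail with sample-variance normalization (beta form)
  p_single <- if (2 * z < n - 1) (1 - 2 * z / (n - 1))^((n - 3) / 2) else 0
  # extreme-value correction for the maximum over the scanned band
  t_eff <- sqrt(4 * pi * stats::var(t))
  tau <- (f2 - f1) * t_eff * sqrt(z) * p_single
  p <- 1 - (1 - p_single) * exp(-tau)
  if (!is.finite(p)) p <- 1
  tibble::tibble(method = "lomb_scargle", period = 1 / f_best,
                 p_value = min(1, max(p, 0)), stat = z)
}

#' JTK-style rank-correlation rhythm test
#'
#' Bins the trace onto a near-uniform grid, then measures Kendall's tau
#' between the binned values and cosine reference templates over a grid of
#' periods and phase lags. Significance is the one-sided normal tail of
#' the best tau, Bonferroni-corrected over the number of templates; a
#' constant (all-ties) trace is degenerate and reported non-rhythmic with
#' p = 1. A monotone trend concords with half of any symmetric template,
#' so detrend first (see [running_mean_detrend()]).
#'
#' @param trace a (detrended) trace.
#' @param period_range c(min, max) period, hours.
#' @param period_step spacing of candidate periods, hours.
#' @param template_step spacing of candidate phase lags, hours.
#' @param bin_width bin width in hours; default `max(1, median sampling)`.
#' @return one-row tibble: `method`, `period`, `lag`, `p_value`, `stat`
#'   (best tau).
#' @export
jtk_test <- function(trace, period_range = c(18, 30), period_step = 2,
                     template_step = 2, bin_width = NULL) {
  trace <- drop_invalid(trace)
  t <- trace$time_hours; x <- trace$value
  bin_width <- bin_width %||% max(1, stats::median(diff(t)))
  bins <- floor((t - t[1]) / bin_width)
  bt <- tapply(t, bins, mean); bx <- tapply(x, bins, mean)
  bt <- as.numeric(bt); bx <- as.numeric(bx)
  n <- length(bx)
  if (n < 8) stopf("only %d bins; >= 8 needed", n)
  if (stats::sd(bx) == 0) {
    return(tibble::tibble(method = "jtk", period = NA_real_, lag = NA_real_,
                          p_value = 1, stat = 0))
  }
  periods <- seq(period_range[1], period_range[2], by = period_step)
  grid <- purrr::map_dfr(periods, function(T) {
    tibble::tibble(period = T, lag = seq(0, T - template_step, by = template_step))
  })
  taus <- purrr::map2_dbl(grid$period, grid$lag, function(T, lag) {
    tmpl <- cos(2 * pi * (bt - lag) / T)
    suppressWarnings(stats::cor(bx, tmpl, method = "kendall"))
  })
  taus[!is.finite(taus)] <- 0
  # one-sided normal tail for Kendall tau under the null
  zs <- 3 * taus * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
  ps <- stats::pnorm(zs, lower.tail = FALSE)
  k <- which.min(ps)
  tibble::tibble(method = "jtk", period = grid$period[k], lag = grid$lag[k],
                 p_value = min(1, ps[k] * nrow(grid)), stat = taus[k])
}

#' Harmonic-regression rhythm test with AR(1) prewhitening
#'
#' Least-squares fit of a single cosine-sine pair at each candidate
#' period; the best period's F statistic is converted to a p-value with
#' the denominator degrees of freedom shrunk by the residual lag-one
#' autocorrelation (effective sample size `n (1 - rho) / (1 + rho)`),
#' then Bonferroni-corrected over candidate periods. This fills the
#' autoregressive-spectral slot of a three-member meta test without
#' depending on any one package's internals.
#'
#' @param trace a (detrended) trace.
#' @param period_range c(min, max) period, hours.
#' @param period_step candidate-period spacing, hours.
#' @return one-row tibble: `method`, `period`, `p_value`, `stat` (F).
#' @export
harmonic_test <- function(trace, period_range = c(18, 30), period_step = 1) {
  trace <- drop_invalid(trace)
  t <- trace$time_hours; x <- trace$value
  n <- length(x)
  if (n < 8) stopf("only %d samples; >= 8 needed", n)
  if (stats::sd(x) == 0) {
    return(tibble::tibble(method = "harmonic", period = NA_real_,
                          p_value = 1, stat = 0))
  }
  periods <- seq(period_range[1], period_range[2], by = period_step)
  sse0 <- sum((x - mean(x))^2)
  fits <- purrr::map_dfr(periods, function(T) {
    X <- cbind(1, cos(2 * pi * t / T), sin(2 * pi * t / T))
    r <- stats::lm.fit(X, x)$residuals
    tibble::tibble(period = T, sse = sum(r^2))
  })
  k <- which.min(fits$sse)
  r <- stats::lm.fit(cbind(1, cos(2 * pi * t / fits$period[k]),
                           sin(2 * pi * t / fits$period[k])), x)$residuals
  rho <- max(0, stats::cor(r[-1], r[-n]))
  n_eff <- max(8, n * (1 - rho) / (1 + rho))
  Fstat <- ((sse0 - fits$sse[k]) / 2) / (fits$sse[k] / (n - 3))
  Fadj <- ((sse0 - fits$sse[k]) / 2) / (fits$sse[k] / max(5, n_eff - 3))
  p <- stats::pf(Fadj, 2, max(5, n_eff - 3), lower.tail = FALSE)
  tibble::tibble(method = "harmonic", period = fits$period[k],
                 p_value = min(1, p * length(periods)), stat = Fstat)
}

#' Combine rhythm-test results
#'
#' Fisher's method on the member p-values (the documented default
#' integration of multi-algorithm rhythm screens) and an integrated
#' period: the arithmetic mean of member periods weighted by `-log(p)`.
#' A single member is returned unchanged.
#'
#' @param results tibble with columns `method`, `period`, `p_value` (one
#'   row per member test), or a list of such one-row tibbles.
#' @return one-row tibble: `method = "meta"`, `period`, `p_value`.
#' @export
meta_combine <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(results)
  }
  if (nrow(results) == 0) stopf("no member results to combine")
  if (nrow(results) == 1) {
    return(tibble::tibble(method = "meta", period = results$period,
                          p_value = results$p_value))
  }
  p <- pmin(pmax(results$p_value, 1e-300), 1)
  chisq <- -2 * sum(log(p))
  p_comb <- stats::pchisq(chisq, df = 2 * length(p), lower.tail = FALSE)
  w <- pmax(-log(p), 1e-6)
  ok <- is.finite(results$period)
  period <- if (any(ok)) stats::weighted.mean(results$period[ok], w[ok]) else NA_real_
  tibble::tibble(method = "meta", period = period, p_value = p_comb)
}

#' Circadian classification rule
#'
#' A trace is classified circadian when its (integrated) period falls in
#' the stated band and its p-value is strictly below `alpha`.
#'
#' @param meta one-row result tibble with `period` and `p_value`, or a
#'   numeric period (then supply `p_value`).
#' @param p_value p-value when `meta` is numeric.
#' @param period_range inclusive period band, hours.
#' @param alpha significance level (strict inequality).
#' @return logical.
#' @export
classify_circadian <- function(meta, p_value = NULL,
                               period_range = c(18, 30), alpha = 0.05) {
  if (is.data.frame(meta)) {
    period <- meta$period; p_value <- meta$p_value
  } else {
    period <- meta
  }
  isTRUE(is.finite(period) && period >= period_range[1] &&
           period <= period_range[2] && p_value < alpha)
}

#' Meta rhythm test
#'
#' Runs the three member tests ([lomb_scargle_test()], [jtk_test()],
#' [harmonic_test()]) on a detrended trace, combines their p-values, and
#' applies [classify_circadian()]. The member tests share the data, so
#' their p-values are strongly positively dependent; the default
#' combination is therefore Sidak on the minimum member p-value,
#' `1 - (1 - min p)^3`, which keeps the false-positive rate of the
#' combined screen at or below the nominal level under positive
#' dependence. `combine = "fisher"` gives the classical independence
#' combination of [meta_combine()] instead (slightly liberal here). The
#' integrated period is the `-log(p)`-weighted mean of the member
#' periods in either mode.
#'
#' @inheritParams lomb_scargle_test
#' @inheritParams classify_circadian
#' @param combine `"sidak"` (default) or `"fisher"`.
#' @return one-row tibble: `period`, `p_value`, `is_circadian`,
#'   `method = "meta"`, plus a `tests` list-column with the member
#'   results.
#' @export
meta_rhythm_test <- function(trace, period_range = c(18, 30), alpha = 0.05,
                             combine = c("sidak", "fisher")) {
  combine <- match.arg(combine)
  members <- dplyr::bind_rows(
    lomb_scargle_test(trace, period_range),
    jtk_test(trace, period_range),
    harmonic_test(trace, period_range))
  meta <- meta_combine(members)
  if (combine == "sidak") {
    meta$p_value <- 1 - (1 - min(members$p_value))^nrow(members)
  }
  tibble::tibble(period = meta$period, p_value = meta$p_value,
                 is_circadian = classify_circadian(meta,
                                                   period_range = period_range,
                                                   alpha = alpha),
                 method = "meta", tests = list(members))
}
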