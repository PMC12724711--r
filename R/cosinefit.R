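#' Damped-cosine fit
#'
#' Least-squares fit of `mesor + A exp(-d t) cos(2 pi (t - t0) / T)` to a
#' fit window (days 2-5 by default, skipping the post-explant transient).
#' For fixed period and damping the model is linear in mesor and the two
#' quadrature amplitudes, so the fit profiles those out analytically and
#' optimizes only `(T, d)` by bounded quasi-Newton from a multi-start grid
#' (periods 20-28 h, two damping starts); the lowest-SSE convergent start
#' wins. Goodness is the Pearson correlation between fit and data on the
#' window, and a trace is classified circadian when the period lies in
#' `period_range` and goodness exceeds `goodness_min` (the r > 0.70 rule).
#'
#' @param trace a trace whose span contains `fit_window`.
#' @param fit_window c(start, end) hours of the fit window.
#' @param period_range free-period bounds for the optimizer, hours.
#' @param classify_range period band of the circadian classification.
#' @param goodness_min correlation threshold of the classification
#'   (strict inequality).
#' @param max_damping upper bound for the damping rate, per hour.
#' @return a `damped_cosine_fit` object; see [glance.damped_cosine_fit()]
#'   for the one-row summary. Fields: `mesor`, `amplitude` (at window
#'   start), `damping_rate`, `period`, `peak_time` (first fitted peak at
#'   or after the window start, hours), `peak_phase_zt`, `goodness`,
#'   `is_circadian`, `converged`, `degenerate`.
#' @export
fit_damped_cosine <- function(trace, fit_window = c(48, 120),
                              period_range = c(16, 32),
                              classify_range = c(18, 30),
                              goodness_min = 0.70, max_damping = 0.2) {
  trace <- drop_invalid(trace)
  rng <- range(trace$time_hours)
  if (fit_window[1] < rng[1] - 1e-9 || fit_window[2] > rng[2] + 1e-9) {
    stopf("fit window [%g, %g] h lies outside the record [%g, %g] h",
          fit_window[1], fit_window[2], rng[1], rng[2])
  }
  keep <- trace$time_hours >= fit_window[1] & trace$time_hours <= fit_window[2]
  if (sum(keep) < 12) stopf("fit window contains only %d samples", sum(keep))
  t0ref <- fit_window[1]
  t <- trace$time_hours[keep] - t0ref   # window-relative time, better conditioned
  x <- trace$value[keep]

  profile_fit <- function(par) {
    T <- par[1]; d <- par[2]
    z <- exp(-d * t); w <- 2 * pi / T
    X <- cbind(1, z * cos(w * t), z * sin(w * t))
    f <- stats::lm.fit(X, x)
    list(sse = sum(f$residuals^2), coef = f$coefficients, fitted = X %*% f$coefficients)
  }
  sse_of <- function(par) profile_fit(par)$sse

  starts <- expand.grid(T = c(20, 22, 24, 26, 28), d = c(0.001, 0.02))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(c(starts$T[i], starts$d[i]), sse_of, method = "L-BFGS-B",
                   lower = c(period_range[1], 0),
                   upper = c(period_range[2], max_damping)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  out <- structure(list(window = fit_window, n = length(x),
                        zt0_offset = zt0_offset(trace),
                        data = tibble::tibble(time_hours = t + t0ref, value = x)),
                   class = "damped_cosine_fit")
  if (is.null(best)) {
    out[c("mesor", "amplitude", "damping_rate", "period", "peak_time",
          "peak_phase_zt", "goodness")] <- NA_real_
    out$converged <- FALSE; out$degenerate <- TRUE; out$is_circadian <- FALSE
    return(out)
  }
  pf <- profile_fit(best$par)
  T <- best$par[1]; d <- best$par[2]
  b <- unname(pf$coef[2]); c0 <- unname(pf$coef[3])
  A <- sqrt(b^2 + c0^2)
  phi <- atan2(c0, b)                       # peak at w * t = phi (window time)
  peak_rel <- wrap_zt(phi * T / (2 * pi), T) # first peak >= window start
  peak_abs <- peak_rel + t0ref
  goodness <- suppressWarnings(stats::cor(as.vector(pf$fitted), x))
  degenerate <- !is.finite(goodness) || A < 1e-8 * max(1, stats::sd(x))
  if (!is.finite(goodness)) goodness <- 0
  out$mesor <- unname(pf$coef[1])
  out$amplitude <- A
  out$damping_rate <- d
  out$period <- T
  out$peak_time <- peak_abs
  out$peak_phase_zt <- wrap_zt(peak_abs - zt0_offset(trace))
  out$goodness <- goodness
  out$converged <- best$convergence == 0
  out$degenerate <- degenerate
  out$is_circadian <- !degenerate && T >= classify_range[1] &&
    T <= classify_range[2] && goodness > goodness_min
  out$fitted <- tibble::tibble(time_hours = t + t0ref,
                               fitted = as.vector(pf$fitted))
  out
}

#' @export
print.damped_cosine_fit <- function(x, ...) {
  if (isTRUE(x$degenerate) && !is.finite(x$period %||% NA)) {
    cat("<damped_cosine_fit> fit failure (degenerate)\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("<damped_cosine_fit> T = %.2f h, peak ZT %.2f, ",
                     "A = %.3g, d = %.4f /h, r = %.3f, circadian: %s\n"),
              x$period, x$peak_phase_zt, x$amplitude, x$damping_rate,
              x$goodness, x$is_circadian))
  invisible(x)
}

#' Daily peak times of a detrended trace
#'
#' Splits the record into Zeitgeber days (windows between successive ZT0
#' crossings), low-pass smooths the series (2-h cutoff, skipped when the
#' sampling is too sparse to support it), and reports each day's maximum,
#' refined by three-point quadratic interpolation around the top sample.
#' Candidate maxima closer than `merge_window` are merged keeping the
#' larger (ties keep the earlier). Days whose median sampling interval
#' exceeds `max_sampling` are omitted, as are days with no valid samples
#' and days whose valid data cover less than `min_coverage` hours of the
#' window (a heavily truncated window pins its maximum to the data edge,
#' an artifact rather than a peak).
#'
#' @param trace a detrended trace.
#' @param smooth_cutoff low-pass cutoff, hours (uniform grids only).
#' @param max_sampling omit days sampled more coarsely than this (hours).
#' @param merge_window merge radius for near-duplicate maxima, hours.
#' @param min_coverage minimum data span within a day window, hours.
#' @return a tibble (`day`, `time_zt`, `time_hours`, `value`), one row per
#'   reported day; days are numbered from the first ZT0 at or before the
#'   record start.
#' @export
daily_peak_times <- function(trace, smooth_cutoff = 2, max_sampling = 4,
                             merge_window = 4, min_coverage = 18) {
  trace <- drop_invalid(trace)
  t <- trace$time_hours; x <- trace$value
  if (diff(range(t)) < 24) stopf("record must span >= 24 h")
  zt0 <- zt0_offset(trace)
  if (is_uniform_grid(t)) {
    dt <- stats::median(diff(t))
    if (smooth_cutoff > 2 * dt && length(t) > 8) {
      x <- sinc_lowpass(x, smooth_cutoff, dt)
    }
  }
  first0 <- zt0 + 24 * floor((t[1] - zt0) / 24)
  edges <- seq(first0, t[length(t)] + 24, by = 24)
  out <- purrr::map_dfr(seq_len(length(edges) - 1L), function(d) {
    inw <- which(t >= edges[d] & t < edges[d + 1])
    if (length(inw) < 3) return(NULL)
    if (stats::median(diff(t[inw])) > max_sampling) return(NULL)
    if (diff(range(t[inw])) < min_coverage) return(NULL)
    ti <- t[inw]; xi <- x[inw]
    # local maxima (plateau-safe: strictly greater than one side, >= other)
    is_max <- vapply(seq_along(xi), function(i) {
      l <- if (i > 1) xi[i - 1] else -Inf
      r <- if (i < length(xi)) xi[i + 1] else -Inf
      xi[i] >= l && xi[i] > r || (xi[i] > l && xi[i] >= r)
    }, logical(1))
    cand <- which(is_max)
    if (!length(cand)) cand <- which.max(xi)
    peaks <- tibble::tibble(time = ti[cand], value = xi[cand], idx = cand)
    # merge candidates closer than merge_window, keeping the larger
    # (earlier on ties); then keep the day's largest
    peaks <- peaks[order(-peaks$value, peaks$time), ]
    kept <- peaks[0, ]
    for (i in seq_len(nrow(peaks))) {
      if (!nrow(kept) || all(abs(kept$time - peaks$time[i]) >= merge_window)) {
        kept <- dplyr::bind_rows(kept, peaks[i, ])
      }
    }
    top <- kept[1, ]
    # quadratic refinement around the top sample (interior, uniform-ish)
    i0 <- top$idx
    tt <- top$time; vv <- top$value
    if (i0 > 1 && i0 < length(xi)) {
      y1 <- xi[i0 - 1]; y2 <- xi[i0]; y3 <- xi[i0 + 1]
      h1 <- ti[i0] - ti[i0 - 1]; h2 <- ti[i0 + 1] - ti[i0]
      if (abs(h1 - h2) < 1e-6 * h1) {
        denom <- y1 - 2 * y2 + y3
        if (denom < 0) {
          delta <- 0.5 * (y1 - y3) / denom * h1
          delta <- max(min(delta, h1), -h1)
          tt <- ti[i0] + delta
          vv <- y2 - 0.25 * (y1 - y3) * delta / h1
        }
      }
    }
    tibble::tibble(day = d, time_zt = wrap_zt(tt - zt0), time_hours = tt,
                   value = vv)
  })
  out
}

#' Peak-to-trough amplitude
#'
#' Maximum minus minimum of the (optionally smoothed) trace within a fixed
#' window after recording onset (36-60 h by default, the second recorded
#' cycle).
#'
#' @param trace a trace containing the window.
#' @param window c(start, end) hours.
#' @param smooth_cutoff optional low-pass cutoff in hours (uniform grids).
#' @return the amplitude (signal units).
#' @export
peak_trough_amplitude <- function(trace, window = c(36, 60),
                                  smooth_cutoff = NULL) {
  trace <- drop_invalid(trace)
  t <- trace$time_hours; x <- trace$value
  if (window[1] < t[1] || window[2] > t[length(t)]) {
    stopf("window [%g, %g] h lies outside the record [%g, %g] h",
          window[1], window[2], t[1], t[length(t)])
  }
  if (!is.null(smooth_cutoff) && is_uniform_grid(t)) {
    x <- sinc_lowpass(x, smooth_cutoff, stats::median(diff(t)))
  }
  inw <- t >= window[1] & t <= window[2]
  max(x[inw]) - min(x[inw])
}
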