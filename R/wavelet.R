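# Morlet continuous wavelet transform on a uniform grid.
# Returns complex matrix [period, time]. omega0 is the time-frequency
# resolution parameter; periods relate to scales via the standard Morlet
# Fourier factor 4*pi / (omega0 + sqrt(2 + omega0^2)). The series is
# extended by reflection before the FFT: zero padding right-shifts the
# effective phase estimate near the record edges, which inflates apparent
# phase coherence there; reflection keeps edge phases local.
morlet_cwt <- function(x, dt, periods, omega0 = 6) {
  n <- length(x)
  xr <- c(x, rev(x))
  npad <- 2^ceiling(log2(length(xr)))
  xp <- c(xr - mean(xr), rep(0, npad - length(xr)))
  fx <- stats::fft(xp)
  omega <- 2 * pi * (0:(npad - 1)) / (npad * dt)
  omega[omega > pi / dt] <- omega[omega > pi / dt] - 2 * pi / dt
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- periods / fourier_factor
  W <- matrix(0i, length(periods), n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- pi^(-1 / 4) * sqrt(2 * pi * s / dt) *
      exp(-((s * omega - omega0)^2) / 2) * (omega > 0)
    w <- stats::fft(fx * psi, inverse = TRUE) / npad
    W[j, ] <- w[1:n]
  }
  W
}

#' Instantaneous phase by continuous wavelet transform
#'
#' Morlet transform of a uniformly sampled (detrended) series over a
#' circadian period band; the ridge is the per-time power maximum across
#' periods, and the instantaneous phase is the complex argument along the
#' ridge, with phase 0 at the waveform maximum (so wavelet phase is
#' directly comparable with peak times). Samples closer to either record
#' edge than one ridge period are flagged as edge-contaminated
#' (`in_coi = FALSE`): one period is about one standard deviation of the
#' Morlet temporal envelope at that scale, a guard band wide enough that
#' the reflection-extended transform is dominated by real data. The
#' series is standardized internally, so `power` is per unit variance.
#'
#' @param trace a trace (or any data frame with `time_hours`, `value`) on
#'   a uniform grid spanning at least twice the longest period sought.
#' @param period_band c(min, max) period, hours.
#' @param n_periods size of the period grid.
#' @param omega0 Morlet time-frequency resolution parameter.
#' @return tibble: `time_hours`, `phase` (radians in `(-pi, pi]`),
#'   `ridge_period` (hours), `power` (ridge power), `in_coi` (TRUE when
#'   clear of the cone of influence).
#' @export
wavelet_phase <- function(trace, period_band = c(18, 30), n_periods = 40,
                          omega0 = 6) {
  trace <- drop_invalid(trace)
  t <- trace$time_hours; x <- trace$value
  if (!is_uniform_grid(t)) {
    stopf("wavelet_phase requires a uniform grid; resample first")
  }
  dt <- stats::median(diff(t))
  span <- diff(range(t))
  if (span < 2 * period_band[2]) {
    stopf("record spans %.1f h; >= %.0f h needed for periods up to %g h",
          span, 2 * period_band[2], period_band[2])
  }
  s <- stats::sd(x)
  if (s == 0) stopf("constant series has no phase")
  periods <- exp(seq(log(period_band[1]), log(period_band[2]),
                     length.out = n_periods))
  W <- morlet_cwt((x - mean(x)) / s, dt, periods, omega0)
  pow <- Mod(W)^2
  ridge <- apply(pow, 2, which.max)
  sel <- cbind(ridge, seq_along(t))
  ridge_period <- periods[ridge]
  edge <- pmin(t - t[1], t[length(t)] - t)
  tibble::tibble(time_hours = t, phase = Arg(W[sel]),
                 ridge_period = ridge_period, power = pow[sel],
                 in_coi = edge >= ridge_period)
}

#' Wavelet phase for every pixel of a pixel-series table
#'
#' Applies [wavelet_phase()] per pixel of the long table produced by
#' [extract_pixel_series()], after optional resampling to a uniform grid
#' and sinc detrending/smoothing.
#'
#' @param pixels long tibble (`pixel`, `time_hours`, `value`).
#' @param resample_dt resample interval in hours (`NULL` to use the data
#'   grid as is); resampling is linear interpolation.
#' @param detrend_cutoff,smooth_cutoff sinc conditioning applied per pixel
#'   before the transform (`NULL` skips).
#' @inheritParams wavelet_phase
#' @return long tibble: `pixel`, `time_hours`, `phase`, `ridge_period`,
#'   `power`, `in_coi`.
#' @export
pixel_wavelet_phase <- function(pixels, period_band = c(18, 30),
                                resample_dt = 1, detrend_cutoff = 48,
                                smooth_cutoff = 4, n_periods = 40,
                                omega0 = 6) {
  pixels |>
    dplyr::group_by(.data$pixel) |>
    dplyr::group_modify(function(df, key) {
      ser <- if (is.null(resample_dt)) {
        tibble::tibble(time_hours = df$time_hours, value = df$value)
      } else {
        resample_uniform(df$time_hours, df$value, resample_dt)
      }
      if (!is.null(detrend_cutoff)) {
        ser <- sinc_detrend_smooth(ser, detrend_cutoff, smooth_cutoff)
      }
      wavelet_phase(ser, period_band, n_periods = n_periods, omega0 = omega0)
    }) |>
    dplyr::ungroup()
}

#' Kuramoto order parameter
#'
#' First-order order parameter of a phase ensemble: the modulus of the
#' mean unit complex exponential, `r = |mean(exp(i theta))|`, ranging from
#' 0 (complete desynchrony) to 1 (total synchrony). Invariant under a
#' global phase rotation. Undefined for fewer than two phases (an error,
#' never a silent 1).
#'
#' @param phases numeric radians (finite; NAs dropped).
#' @return `r` in `[0, 1]`.
#' @export
kuramoto_order <- function(phases) {
  phases <- phases[is.finite(phases)]
  if (length(phases) < 2) {
    stopf("the order parameter needs >= 2 phases (got %d)", length(phases))
  }
  min(1, Mod(mean(exp(1i * phases))))
}
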