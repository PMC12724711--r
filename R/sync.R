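#' Synchrony time course from per-pixel phases
#'
#' Applies [kuramoto_order()] per time point across the units (pixels) of
#' a phase table, using only samples clear of the cone of influence. A
#' quality gate excludes pixels whose median ridge power falls below the
#' 5th percentile of a white-noise ridge-power null (computed once per
#' call from internally seeded white-noise series of matching length --
#' deterministic); ungated dead pixels would bias the index downward.
#' `r` is reported only where at least two units contribute; by default
#' (`common_window = TRUE`) only time points where *every* gated unit is
#' clear of the cone are reported, because units enter the cone boundary
#' at phase-dependent times and a changing ensemble composition there
#' masquerades as a synchrony change. The series is optionally smoothed
#' with a centred rolling mean.
#'
#' @param phases long tibble from [pixel_wavelet_phase()] (columns
#'   `pixel`, `time_hours`, `phase`, `power`, `in_coi`).
#' @param smooth_hours width of the rolling-mean smoother (0 disables).
#' @param respect_coi drop edge-contaminated samples first.
#' @param power_gate apply the white-noise quality gate.
#' @param common_window restrict to times where all gated units
#'   contribute.
#' @return tibble: `time_hours`, `r` in `[0, 1]`, `n_units`.
#' @export
sync_timecourse <- function(phases, smooth_hours = 2, respect_coi = TRUE,
                            power_gate = TRUE, common_window = TRUE) {
  stopifnot(all(c("pixel", "time_hours", "phase") %in% names(phases)))
  ph <- phases
  if (respect_coi && "in_coi" %in% names(ph)) ph <- ph[ph$in_coi, ]
  if (!nrow(ph)) {
    warning("no samples outside the cone of influence; empty sync series")
    return(tibble::tibble(time_hours = numeric(), r = numeric(),
                          n_units = integer()))
  }
  if (power_gate && "power" %in% names(ph)) {
    full_t <- sort(unique(phases$time_hours))
    thr <- white_noise_power_q05(n = length(full_t),
                                 dt = stats::median(diff(full_t)))
    med <- ph |>
      dplyr::group_by(.data$pixel) |>
      dplyr::summarise(mp = stats::median(.data$power), .groups = "drop")
    ph <- ph[ph$pixel %in% med$pixel[med$mp >= thr], ]
  }
  out <- ph |>
    dplyr::group_by(.data$time_hours) |>
    dplyr::summarise(n_units = sum(is.finite(.data$phase)),
                     r = if (sum(is.finite(.data$phase)) >= 2) {
                       kuramoto_order(.data$phase)
                     } else NA_real_,
                     .groups = "drop") |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::arrange(.data$time_hours)
  if (common_window && nrow(out)) {
    out <- out[out$n_units == max(out$n_units), ]
  }
  if (!nrow(out)) {
    warning("fewer than two units overlap at every time point")
    return(tibble::tibble(time_hours = numeric(), r = numeric(),
                          n_units = integer()))
  }
  if (smooth_hours > 0 && nrow(out) > 2) {
    out$r <- roll_mean_time(out$time_hours, out$r, smooth_hours)
  }
  out[, c("time_hours", "r", "n_units")]
}

# centred rolling mean over a time window (uneven grids allowed)
roll_mean_time <- function(t, x, window) {
  vapply(seq_along(t), function(i) {
    mean(x[abs(t - t[i]) <= window / 2])
  }, numeric(1))
}

# 5th percentile of the pooled ridge-power distribution of standardized
# white noise, matched to series length/step; a pixel whose typical ridge
# power sits below even this noise floor carries no usable phase.
# Deterministic (local seed) and memoised per geometry.
the <- new.env(parent = emptyenv())
white_noise_power_q05 <- function(n, dt, period_band = c(18, 30), reps = 40) {
  key <- sprintf("%d_%g_%g_%g", n, dt, period_band[1], period_band[2])
  if (!is.null(the[[key]])) return(the[[key]])
  pooled <- withr::with_seed(271828, {
    unlist(lapply(seq_len(reps), function(i) {
      ser <- tibble::tibble(time_hours = seq(0, by = dt, length.out = n),
                            value = stats::rnorm(n))
      wavelet_phase(ser, period_band, n_periods = 20)$power
    }))
  })
  the[[key]] <- unname(stats::quantile(pooled, 0.05))
  the[[key]]
}

#' Rayleigh resultant of a set of peak times
#'
#' Maps clock times on a `modulus`-hour circle to angles and returns the
#' resultant vector length R (1 when every subject peaks at the same time
#' of day, approaching 0 for uniformly scattered peaks -- the
#' inter-pregnancy sync index), the circular mean direction in hours, and
#' the Rayleigh uniformity p-value of [rayleigh_test()] when `n >= 2`.
#' A single observation is degenerate (R = 1) and flagged with a warning.
#'
#' @param peaks tibble with a `time_zt` column (or a numeric vector of
#'   hours).
#' @param modulus circle length, hours.
#' @return one-row tibble: `n`, `R`, `mean_direction` (hours),
#'   `p_uniformity`.
#' @export
rayleigh_stat <- function(peaks, modulus = 24) {
  x <- if (is.data.frame(peaks)) peaks$time_zt else as.numeric(peaks)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 1) stopf("no peak times")
  if (n == 1) warning("Rayleigh R of a single observation is degenerate (R = 1)")
  th <- 2 * pi * x / modulus
  R <- min(1, Mod(mean(exp(1i * th))))
  tibble::tibble(n = n, R = R,
                 mean_direction = circ_mean_hours(x, modulus),
                 p_uniformity = if (n >= 2) rayleigh_test(x, modulus) else NA_real_)
}

#' Rayleigh uniformity test
#'
#' Tests clustering of clock times on the circle: `Z = n R^2`, with the
#' small-sample corrected p-value
#' `p = exp(sqrt(1 + 4 n + 4 (n^2 - Z n)) - (1 + 2 n))`. p < 0.05
#' indicates significant clustering (consistent timing). Fewer than four
#' observations give unstable p-values; a warning is raised.
#'
#' @param peaks tibble with `time_zt` or numeric hours.
#' @param modulus circle length, hours.
#' @return the p-value.
#' @export
rayleigh_test <- function(peaks, modulus = 24) {
  x <- if (is.data.frame(peaks)) peaks$time_zt else as.numeric(peaks)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stopf("the Rayleigh test needs >= 2 observations")
  if (n < 4) warning("Rayleigh p-values are unstable for n < 4")
  th <- 2 * pi * x / modulus
  R <- Mod(mean(exp(1i * th)))
  Z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Z * n)) - (1 + 2 * n))
  min(1, p)
}

#' Circular phase differences between two peak-time sets
#'
#' Per-pair circular difference `a - b` wrapped to `(-12, 12]` hours, with
#' the circular mean of the differences as summary. In paired mode the two
#' sets must carry matching `subject` labels (e.g. uterus and cervix
#' explanted from the same dam); unpaired mode compares circular means.
#'
#' @param a,b tibbles with `time_zt` (and `subject` when paired) or
#'   numeric vectors of hours.
#' @param paired match by subject label.
#' @return list with `differences` (tibble) and `mean_difference` (hours,
#'   in `(-12, 12]`).
#' @export
phase_difference <- function(a, b, paired = TRUE) {
  as_tbl <- function(x, who) {
    if (is.data.frame(x)) {
      tibble::tibble(subject = as.character(x$subject %||% seq_len(nrow(x))),
                     time_zt = x$time_zt)
    } else {
      tibble::tibble(subject = as.character(seq_along(x)), time_zt = as.numeric(x))
    }
  }
  ta <- as_tbl(a, "a"); tb <- as_tbl(b, "b")
  if (paired) {
    if (nrow(ta) != nrow(tb) || !setequal(ta$subject, tb$subject)) {
      stopf("paired mode needs equal-length sets with matching subject labels")
    }
    tb <- tb[match(ta$subject, tb$subject), ]
    d <- wrap_half(ta$time_zt - tb$time_zt)
    diffs <- tibble::tibble(subject = ta$subject, difference = d)
    mean_d <- wrap_half(circ_mean_hours(d))
  } else {
    mean_d <- wrap_half(circ_mean_hours(ta$time_zt) - circ_mean_hours(tb$time_zt))
    diffs <- tibble::tibble(subject = NA_character_, difference = mean_d)
  }
  list(differences = diffs, mean_difference = mean_d)
}
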