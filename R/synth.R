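#' Ground-truth oscillator parameters for simulation
#'
#' One row per simulated oscillating unit (a pregnancy, a pup-sized image
#' region, or an explant). `peak_time` is the Zeitgeber Time of the
#' waveform maximum, `amplitude_rel` the circadian modulation depth as a
#' fraction of the baseline, `damping_rate` the exponential decay of that
#' modulation, and `onset_time` the hours from recording start at which
#' the modulation ramps up (a smooth logistic ramp of width `onset_width`
#' in [sim_scenario()]; rhythms in utero emerge gradually rather than
#' switching on).
#'
#' @param unit_id label.
#' @param period hours, in (0, 48].
#' @param peak_time ZT hours; wrapped to `[0, 24)`.
#' @param amplitude_rel dimensionless, >= 0.
#' @param damping_rate per hour, >= 0.
#' @param onset_time hours from recording start, >= 0.
#' @return a tibble, one row per unit.
#' @export
oscillator_truth <- function(unit_id, period = 24, peak_time = 13,
                             amplitude_rel = 0.5, damping_rate = 0,
                             onset_time = 0) {
  df <- tibble::tibble(unit_id = as.character(unit_id), period, peak_time,
                       amplitude_rel, damping_rate, onset_time)
  if (any(df$period <= 0 | df$period > 48)) stopf("period must be in (0, 48] h")
  if (any(df$amplitude_rel < 0)) stopf("amplitude_rel must be >= 0")
  if (any(df$damping_rate < 0)) stopf("damping_rate must be >= 0")
  if (any(df$onset_time < 0)) stopf("onset_time must be >= 0")
  df$peak_time <- wrap_zt(df$peak_time)
  df
}

#' Simulation scenario
#'
#' Bundles everything the generators need: recording geometry in time,
#' the exponential baseline (photon output grows roughly exponentially
#' across gestation; `growth_rate = log(100)/216` reproduces a 100-fold
#' rise over a 9-day window), the set of true oscillators, the noise
#' model, pixel/pup phase heterogeneity, cosmic-ray spike rate and the
#' shutter schedule for dark counts.
#'
#' @param seed integer RNG seed used by every stochastic generator.
#' @param duration recording length, hours (> 0).
#' @param sampling_interval minutes between samples (> 0).
#' @param baseline0 baseline intensity at t = 0 (counts per sample).
#' @param growth_rate per hour; baseline is `baseline0 * exp(growth_rate * t)`.
#' @param noise `"poisson"` (photon counting), `"gaussian"`, or `"none"`.
#' @param noise_sd standard deviation for Gaussian noise.
#' @param units tibble from [oscillator_truth()].
#' @param phase_dispersion_start,phase_dispersion_end circular SD (hours) of
#'   per-pixel peak times around the unit peak at the start and end of the
#'   record; the dispersion interpolates linearly in between, so an end
#'   value below the start simulates progressive synchronization.
#' @param spike_rate expected cosmic-ray events per frame (images only).
#' @param dark_interval,dark_duration shutter schedule in minutes: the
#'   shutter closes for `dark_duration` every `dark_interval` (e.g. 1 min
#'   every 15 min); `NULL` disables dark intervals.
#' @param dark_rate detector dark counts per minute per sensor.
#' @param zt_start Zeitgeber Time at recording start (hours).
#' @param onset_width width (hours) of the logistic onset ramp.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(seed = 1, duration = 144, sampling_interval = 1,
                         baseline0 = 100, growth_rate = 0,
                         noise = c("poisson", "gaussian", "none"),
                         noise_sd = 1, units = oscillator_truth("u1"),
                         phase_dispersion_start = 0, phase_dispersion_end = 0,
                         spike_rate = 0, dark_interval = NULL,
                         dark_duration = 1, dark_rate = 10, zt_start = 0,
                         onset_width = 12) {
  noise <- match.arg(noise)
  if (duration <= 0) stopf("duration must be > 0")
  if (sampling_interval <= 0) stopf("sampling_interval must be > 0")
  if (nrow(units) < 1) stopf("at least one oscillator unit is required")
  if (phase_dispersion_start < 0 || phase_dispersion_end < 0) {
    stopf("phase dispersions must be >= 0")
  }
  if (spike_rate < 0) stopf("spike_rate must be >= 0")
  structure(list(seed = as.integer(seed), duration = duration,
                 sampling_interval = sampling_interval, baseline0 = baseline0,
                 growth_rate = growth_rate, noise = noise, noise_sd = noise_sd,
                 units = units,
                 phase_dispersion_start = phase_dispersion_start,
                 phase_dispersion_end = phase_dispersion_end,
                 spike_rate = spike_rate, dark_interval = dark_interval,
                 dark_duration = dark_duration, dark_rate = dark_rate,
                 zt_start = zt_start, onset_width = onset_width),
            class = "sim_scenario")
}

# logistic onset ramp: 0 before onset, ~1 after; centred so the ramp
# reaches 1/2 at onset_time + onset_width/2 and is ~0 at onset_time
onset_ramp <- function(t, onset_time, onset_width) {
  if (onset_time <= 0) return(rep(1, length(t)))
  if (onset_width <= 0) return(as.numeric(t >= onset_time))
  stats::plogis((t - onset_time - onset_width / 2) / (onset_width / 8))
}

# noiseless multiplicative modulation of one unit, as a fraction of baseline
unit_modulation <- function(t, u, onset_width, zt_start, phase_shift_h = 0) {
  t0 <- wrap_zt(u$peak_time - zt_start)
  onset_ramp(t, u$onset_time, onset_width) * u$amplitude_rel *
    exp(-u$damping_rate * t) *
    cos(2 * pi * (t - t0 - phase_shift_h) / u$period)
}

scenario_times <- function(scenario) {
  dt <- scenario$sampling_interval / 60
  seq(0, scenario$duration, by = dt)
}

scenario_noise <- function(scenario, lambda) {
  lambda <- pmax(lambda, 0)
  switch(scenario$noise,
         poisson = stats::rpois(length(lambda), lambda),
         gaussian = pmax(lambda + stats::rnorm(length(lambda), 0, scenario$noise_sd), 0),
         none = lambda)
}

zt0_from_start <- function(zt_start) wrap_zt(24 - zt_start)

#' Simulate a dual-sensor photomultiplier recording
#'
#' Emulates continuous luminometry of a freely moving dam: two
#' photomultiplier tubes each see half of an exponentially growing,
#' circadianly modulated photon flux plus their own dark counts; a
#' programmable shutter closes periodically so only dark counts are
#' recorded during those samples. Counts are Poisson by default.
#'
#' @param scenario a [sim_scenario()].
#' @return a list with `trace` (the two sensors summed as recorded, dark
#'   intervals flagged in the `dark` column, dark offset still included),
#'   `sensor_a`/`sensor_b` (per-sensor traces for
#'   [subtract_dark_and_sum()]), `truth` (the unit table) and `scenario`.
#' @export
simulate_pmt_trace <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  withr::local_seed(scenario$seed)
  t <- scenario_times(scenario)
  mins <- t * 60
  dark <- rep(FALSE, length(t))
  if (!is.null(scenario$dark_interval)) {
    dark <- (mins %% scenario$dark_interval) < scenario$dark_duration
  }
  mod <- rowSums(vapply(seq_len(nrow(scenario$units)), function(i) {
    unit_modulation(t, scenario$units[i, ], scenario$onset_width,
                    scenario$zt_start)
  }, numeric(length(t))))
  signal <- pmax(scenario$baseline0 * exp(scenario$growth_rate * t) * (1 + mod), 0)
  dark_counts <- scenario$dark_rate * scenario$sampling_interval
  lam_a <- ifelse(dark, 0, signal / 2) + dark_counts
  lam_b <- ifelse(dark, 0, signal / 2) + dark_counts
  zt0 <- zt0_from_start(scenario$zt_start)
  a <- biolum_trace(t, scenario_noise(scenario, lam_a), dark = dark,
                    zt0_offset = zt0, meta = list(sensor = "A"))
  b <- biolum_trace(t, scenario_noise(scenario, lam_b), dark = dark,
                    zt0_offset = zt0, meta = list(sensor = "B"))
  combined <- biolum_trace(t, a$value + b$value, dark = dark, zt0_offset = zt0)
  list(trace = combined, sensor_a = a, sensor_b = b,
       truth = scenario$units, scenario = scenario)
}

#' Simulate an explant luminometer trace
#'
#' A single tissue explant recorded in discrete bins: slow baseline plus a
#' damped cosine, `baseline(t) + A * exp(-d t) * cos(2 pi (t - t0) / T)`
#' with `A = amplitude_rel * baseline0`, plus counting noise. ZT0 is
#' anchored to the stated lights-on via `zt_start`.
#'
#' @param truth a single-row [oscillator_truth()] tibble.
#' @param scenario a [sim_scenario()]; `sampling_interval = 10` min and
#'   `duration = 120` h are typical.
#' @return a [biolum_trace()]; the truth row is attached as attribute
#'   `truth`.
#' @export
simulate_explant_trace <- function(truth, scenario) {
  stopifnot(inherits(scenario, "sim_scenario"), nrow(truth) == 1)
  withr::local_seed(scenario$seed)
  t <- scenario_times(scenario)
  baseline <- scenario$baseline0 * exp(scenario$growth_rate * t)
  mod <- scenario$baseline0 *
    unit_modulation(t, truth[1, ], scenario$onset_width, scenario$zt_start)
  tr <- biolum_trace(t, scenario_noise(scenario, baseline + mod),
                     zt0_offset = zt0_from_start(scenario$zt_start),
                     meta = list(unit_id = truth$unit_id[1]))
  attr(tr, "truth") <- truth
  tr
}

#' Simulate a bioluminescence image stack
#'
#' Builds a frame sequence in which each rectangular unit region oscillates
#' around its unit's peak time, with per-pixel peak-time offsets drawn from
#' a wrapped normal whose SD interpolates from `phase_dispersion_start` to
#' `phase_dispersion_end` across the record (pixels converge toward the
#' unit phase when the end dispersion is smaller). Adds a flat camera
#' background, optional Gaussian point-spread blur, single-frame
#' cosmic-ray spikes (amplitude 20x the local signal, logged exactly) and
#' counting noise. Frame timestamps default to the scenario's uniform
#' interval; pass `timestamps` (e.g. from [gestation_schedule()]) for the
#' mixed every-12-h-then-every-4-h acquisition.
#'
#' @param scenario a [sim_scenario()] whose `units` have one row per region
#'   in `geometry`.
#' @param geometry list with `dim = c(nrow, ncol)`, `regions` (tibble with
#'   columns `unit_id, row_min, row_max, col_min, col_max`; regions must be
#'   disjoint and inside the frame), optional `background` level (counts),
#'   optional `psf_sigma` (pixels).
#' @param timestamps optional explicit frame times (hours).
#' @return list with `stack` (an [image_stack()] whose ROI is the union of
#'   unit regions and whose background mask is the frame border), and
#'   `truth` (list: `units`, `pixels` with per-pixel `delta0` peak-time
#'   offsets, `spikes` with one row per injected event).
#' @export
simulate_image_stack <- function(scenario, geometry, timestamps = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  withr::local_seed(scenario$seed)
  shp <- as.integer(geometry$dim)
  reg <- geometry$regions
  if (is.null(reg) || nrow(reg) < 1) stopf("geometry must place >= 1 unit region")
  if (any(reg$row_min < 1 | reg$col_min < 1 | reg$row_max > shp[1] |
          reg$col_max > shp[2] | reg$row_min > reg$row_max |
          reg$col_min > reg$col_max)) {
    stopf("unit regions must lie inside the %d x %d frame", shp[1], shp[2])
  }
  occ <- matrix(0L, shp[1], shp[2])
  for (i in seq_len(nrow(reg))) {
    occ[reg$row_min[i]:reg$row_max[i], reg$col_min[i]:reg$col_max[i]] <-
      occ[reg$row_min[i]:reg$row_max[i], reg$col_min[i]:reg$col_max[i]] + 1L
  }
  if (any(occ > 1L)) stopf("unit regions overlap")
  ts <- timestamps %||% scenario_times(scenario)
  if (any(diff(ts) <= 0)) stopf("timestamps must strictly increase")
  background <- geometry$background %||% 5
  psf_sigma <- geometry$psf_sigma %||% 0

  # per-pixel peak-time offsets (hours) around each unit's peak
  pixels <- purrr::map_dfr(seq_len(nrow(reg)), function(i) {
    r <- reg[i, ]
    grid <- expand.grid(row = r$row_min:r$row_max, col = r$col_min:r$col_max)
    d0 <- if (scenario$phase_dispersion_start > 0) {
      wrap_half(stats::rnorm(nrow(grid), 0, scenario$phase_dispersion_start))
    } else rep(0, nrow(grid))
    tibble::tibble(unit_id = r$unit_id, row = grid$row, col = grid$col,
                   delta0 = d0)
  })
  disp_frac <- if (scenario$phase_dispersion_start > 0) {
    s <- scenario$phase_dispersion_start
    e <- scenario$phase_dispersion_end
    (s + (e - s) * (ts - ts[1]) / (ts[length(ts)] - ts[1])) / s
  } else rep(0, length(ts))

  units <- scenario$units
  frames <- array(background, dim = c(shp, length(ts)))
  for (k in seq_along(ts)) {
    t <- ts[k]
    for (i in seq_len(nrow(reg))) {
      u <- units[units$unit_id == reg$unit_id[i], ]
      if (nrow(u) != 1) stopf("no unique truth row for region %s", reg$unit_id[i])
      px <- pixels[pixels$unit_id == reg$unit_id[i], ]
      mod <- unit_modulation(t, u, scenario$onset_width, scenario$zt_start,
                             phase_shift_h = px$delta0 * disp_frac[k])
      vals <- pmax(scenario$baseline0 * exp(scenario$growth_rate * t) *
                     (1 + mod), 0)
      frames[cbind(px$row, px$col, k)] <- frames[cbind(px$row, px$col, k)] + vals
    }
    if (psf_sigma > 0) {
      frames[, , k] <- EBImage::gblur(frames[, , k], sigma = psf_sigma)
    }
  }

  # cosmic-ray spikes: single frame, single pixel, >= 20x local signal
  spikes <- tibble::tibble(frame = integer(), row = integer(), col = integer(),
                           added = numeric())
  if (scenario$spike_rate > 0) {
    for (k in seq_along(ts)) {
      n_sp <- stats::rpois(1, scenario$spike_rate)
      if (n_sp > 0) {
        rows <- sample.int(shp[1], n_sp, replace = TRUE)
        cols <- sample.int(shp[2], n_sp, replace = TRUE)
        add <- 20 * (frames[cbind(rows, cols, k)] + 1)
        frames[cbind(rows, cols, k)] <- frames[cbind(rows, cols, k)] + add
        spikes <- dplyr::bind_rows(spikes,
          tibble::tibble(frame = k, row = rows, col = cols, added = add))
      }
    }
  }
  noisy <- scenario_noise(scenario, as.vector(frames))
  frames <- array(noisy, dim = dim(frames))

  roi <- occ > 0L
  bg <- matrix(FALSE, shp[1], shp[2])
  bg[c(1, shp[1]), ] <- TRUE
  bg[, c(1, shp[2])] <- TRUE
  bg <- bg & !roi
  stack <- image_stack(frames, ts, roi_mask = roi, background_mask = bg,
                       zt0_offset = zt0_from_start(scenario$zt_start))
  list(stack = stack,
       truth = list(units = units, pixels = pixels, spikes = spikes,
                    background = background),
       scenario = scenario)
}

#' Gestational acquisition schedule
#'
#' Frame times (hours from recording start) for the mixed imaging cadence:
#' one frame every `early_step` hours up to `switch_at`, then every
#' `late_step` hours until `end`.
#'
#' @param switch_at,end hours from recording start.
#' @param early_step,late_step hours.
#' @return numeric vector of hours.
#' @export
gestation_schedule <- function(switch_at = 144, end = 216, early_step = 12,
                               late_step = 4) {
  unique(c(seq(0, switch_at, by = early_step),
           seq(switch_at, end, by = late_step)))
}

# von Mises sampler (Best & Fisher 1979 rejection method); kappa = 0 is uniform
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa > 500) return(rep(mu, n) + stats::rnorm(n, 0, 1 / sqrt(kappa)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  atan2(sin(out), cos(out))
}

#' Simulate a set of daily peak times
#'
#' Draws peak times from a von Mises distribution on the 24-h circle,
#' the natural model for clustered daily peak times across subjects.
#' `concentration = 0` gives uniform (fully desynchronized) peaks; large
#' values collapse onto `mean_peak`.
#'
#' @param n number of subjects (>= 1).
#' @param mean_peak ZT hours of the mean direction.
#' @param concentration von Mises kappa (>= 0).
#' @param seed RNG seed.
#' @return tibble with columns `subject`, `time_zt`.
#' @export
simulate_peak_times <- function(n, mean_peak = 13, concentration = 2, seed = 1) {
  if (n < 1) stopf("n must be >= 1")
  if (concentration < 0) stopf("concentration must be >= 0")
  withr::local_seed(seed)
  th <- rvonmises(n, 2 * pi * mean_peak / 24, concentration)
  tibble::tibble(subject = sprintf("s%03d", seq_len(n)),
                 time_zt = wrap_zt(th * 24 / (2 * pi)))
}
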