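as_stack <- function(x) {
  if (inherits(x, "image_stack")) return(x)
  if (is.list(x) && inherits(x$stack, "image_stack")) return(x$stack)
  stopf("expected an image_stack (or a simulation result containing one)")
}

# the densely sampled tail of a trace (median step <= max_step), for the
# rhythm statistics that need near-uniform sampling
dense_tail <- function(trace, max_step = 4) {
  t <- trace$time_hours
  d <- diff(t)
  i <- length(d)
  while (i >= 1 && d[i] <= max_step + 1e-9) i <- i - 1
  trace[(i + 1L):nrow(trace), , drop = FALSE]
}

dam_rhythm <- function(flux, period_range, alpha, detrend_window = 24,
                       dense_step = 4) {
  det <- running_mean_detrend(flux, detrend_window)
  seg <- dense_tail(drop_invalid(det), dense_step)
  if (nrow(seg) < 8 || diff(range(seg$time_hours)) < 2 * period_range[1]) {
    return(list(det = det, test = NULL,
                reason = "insufficient dense sampling for rhythm test"))
  }
  seg <- rewrap_trace(seg, det)
  list(det = det, test = meta_rhythm_test(seg, period_range, alpha),
       reason = NA_character_)
}

# keep only the densely sampled tail of a stack (frame spacing <= max_step):
# sparse early-gestation frames cannot support instantaneous-phase
# estimation at circadian periods
stack_dense_tail <- function(stack, max_step = 4) {
  d <- diff(stack$timestamps)
  i <- length(d)
  while (i >= 1 && d[i] <= max_step + 1e-9) i <- i - 1
  keep <- (i + 1L):length(stack$timestamps)
  stack$frames <- stack$frames[, , keep, drop = FALSE]
  stack$timestamps <- stack$timestamps[keep]
  stack
}

# per-dam pixel synchrony series: minimize -> background subtract ->
# Gaussian pixel extraction -> resample -> sinc condition -> wavelet ->
# Kuramoto
dam_sync_series <- function(stack, gaussian_sigma = 1, resample_dt = 1,
                            detrend_cutoff = 48, smooth_cutoff = 4,
                            band = c(18, 30), smooth_hours = 2,
                            power_gate = TRUE, dense_step = NULL) {
  if (!is.null(dense_step)) stack <- stack_dense_tail(stack, dense_step)
  st <- adjacent_frame_minimize(stack)
  st <- background_subtract(st)
  px <- extract_pixel_series(st, gaussian_sigma = gaussian_sigma)
  ph <- pixel_wavelet_phase(px, period_band = band, resample_dt = resample_dt,
                            detrend_cutoff = detrend_cutoff,
                            smooth_cutoff = smooth_cutoff)
  sync_timecourse(ph, smooth_hours = smooth_hours, power_gate = power_gate)
}

new_study_report <- function(kind, params, seed, ...) {
  structure(c(list(kind = kind, params = params, seed = seed,
                   config_hash = rlang::hash(list(kind = kind, params = params,
                                                  seed = seed)),
                   version = pkg_version()),
              list(...)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: %s> lucisync %s, config %s\n", x$kind,
              x$version, substr(x$config_hash, 1, 8)))
  if (!is.null(x$fits)) {
    cat(sprintf("  %d subjects, %d circadian, %d excluded\n",
                nrow(x$fits), sum(x$fits$is_circadian, na.rm = TRUE),
                nrow(x$exclusions %||% data.frame())))
  }
  if (!is.null(x$rayleigh_daily) && nrow(x$rayleigh_daily)) {
    f <- x$rayleigh_daily[nrow(x$rayleigh_daily), ]
    cat(sprintf("  final-day inter-subject Rayleigh R = %.3f (n = %d)\n",
                f$R, f$n))
  }
  invisible(x)
}

#' In utero imaging study
#'
#' Runs the whole-abdomen imaging analysis for a set of pregnant dams:
#' adjacent-frame minimization, optional frame averaging, background-
#' subtracted ROI photon flux, 24-h running-mean detrending, the
#' three-member meta rhythm test on the densely sampled late-gestation
#' segment, and the 18-30 h / p < 0.05 circadian classification. Dams
#' failing classification are excluded from the peak and synchrony
#' summaries but listed with a machine-readable reason. For circadian
#' dams the report carries daily peak times, the day-by-day
#' inter-pregnancy Rayleigh sync index across dams, and the per-dam
#' intra-pregnancy Kuramoto sync series from pixel-level wavelet phases.
#'
#' @param dams named list of [image_stack()] objects (or
#'   [simulate_image_stack()] results).
#' @param period_range,alpha circadian classification rule.
#' @param average_n frames per averaging block (1 = none).
#' @param gaussian_sigma pixel-extraction Gaussian SD, pixels.
#' @param resample_dt uniform grid for the wavelet, hours.
#' @param detrend_cutoff,smooth_cutoff sinc conditioning of pixel series,
#'   hours.
#' @param sync_smooth_hours rolling-mean width of the sync series, hours.
#' @param sync_dense_step pixel synchrony is computed on the densely
#'   sampled tail of each stack (frame spacing at most this many hours);
#'   sparser early-gestation frames cannot support instantaneous phase at
#'   circadian periods.
#' @param seed recorded in the report (the pipeline itself is
#'   deterministic given its inputs).
#' @return a `study_report` with elements `fits`, `exclusions`, `peaks`,
#'   `rayleigh_daily`, `sync`.
#' @export
run_inutero <- function(dams, period_range = c(18, 30), alpha = 0.05,
                        average_n = 1, gaussian_sigma = 1, resample_dt = 1,
                        detrend_cutoff = 48, smooth_cutoff = 4,
                        sync_smooth_hours = 2, sync_dense_step = 4, seed = 1) {
  stopifnot(length(dams) >= 1, !is.null(names(dams)))
  params <- list(period_range = period_range, alpha = alpha,
                 average_n = average_n, gaussian_sigma = gaussian_sigma,
                 resample_dt = resample_dt, detrend_cutoff = detrend_cutoff,
                 smooth_cutoff = smooth_cutoff,
                 sync_smooth_hours = sync_smooth_hours,
                 sync_dense_step = sync_dense_step)
  fits <- list(); exclusions <- list(); peaks <- list(); sync <- list()
  for (dam in names(dams)) {
    stack <- as_stack(dams[[dam]])
    st <- adjacent_frame_minimize(stack)
    if (average_n > 1) st <- frame_average(st, average_n)
    flux <- roi_flux(st)
    rh <- dam_rhythm(flux, period_range, alpha)
    if (is.null(rh$test)) {
      fits[[dam]] <- tibble::tibble(subject = dam, period = NA_real_,
                                    p_value = NA_real_, is_circadian = FALSE)
      exclusions[[dam]] <- tibble::tibble(subject = dam, reason = rh$reason)
      next
    }
    fits[[dam]] <- tibble::tibble(subject = dam, period = rh$test$period,
                                  p_value = rh$test$p_value,
                                  is_circadian = rh$test$is_circadian)
    if (!rh$test$is_circadian) {
      exclusions[[dam]] <- tibble::tibble(
        subject = dam,
        reason = sprintf("not circadian (period %.1f h, p = %.3g)",
                         rh$test$period, rh$test$p_value))
      next
    }
    pk <- daily_peak_times(rh$det)
    if (nrow(pk)) peaks[[dam]] <- dplyr::mutate(pk, subject = dam,
                                                .before = 1)
    sc <- dam_sync_series(stack, gaussian_sigma, resample_dt, detrend_cutoff,
                          smooth_cutoff, period_range, sync_smooth_hours,
                          dense_step = sync_dense_step)
    if (nrow(sc)) sync[[dam]] <- dplyr::mutate(sc, subject = dam, .before = 1)
  }
  peaks <- dplyr::bind_rows(peaks)
  empty_rayleigh <- tibble::tibble(day = integer(), n = integer(),
                                   R = numeric(), mean_direction = numeric(),
                                   p_uniformity = numeric())
  rayleigh_daily <- if (nrow(peaks)) {
    eligible <- peaks |>
      dplyr::count(.data$day) |>
      dplyr::filter(.data$n >= 2)
    if (nrow(eligible)) {
      purrr::map_dfr(eligible$day, function(d) {
        dplyr::mutate(rayleigh_stat(peaks[peaks$day == d, ]), day = d,
                      .before = 1)
      })
    } else empty_rayleigh
  } else empty_rayleigh
  if (!nrow(rayleigh_daily)) {
    warning("fewer than two circadian dams; synchrony sections are empty")
  }
  new_study_report("inutero", params, seed,
                   fits = dplyr::bind_rows(fits),
                   exclusions = dplyr::bind_rows(exclusions),
                   peaks = peaks, rayleigh_daily = rayleigh_daily,
                   sync = dplyr::bind_rows(sync))
}

#' Explant luminometry study
#'
#' Fits the damped cosine to days 2-5 of each explant trace, classifies
#' circadian traces by the 18-30 h period band and goodness r > 0.70,
#' extracts the 36-60 h peak-to-trough amplitude and the ZT peak phase,
#' tests peak-time clustering across explants (per tissue when tissue
#' labels are supplied) with the Rayleigh uniformity test, and, when a
#' tissue pair is requested, reports paired circular phase differences
#' between tissues from the same subject. Traces too short for the fit
#' window fail individually; the run continues.
#'
#' @param traces named list of traces, or one long tibble with an `id`
#'   column.
#' @param meta optional tibble (`id`, `subject`, `tissue`).
#' @param fit_window,amplitude_window hours.
#' @param period_range classification band, hours.
#' @param goodness_min classification correlation threshold.
#' @param pair optional c(tissue_a, tissue_b) for paired phase
#'   differences (reported as a - b).
#' @param seed recorded in the report.
#' @return a `study_report` with `fits`, `exclusions`, `rayleigh`,
#'   `pair_difference`, and the fit objects in `models`.
#' @export
run_explant <- function(traces, meta = NULL, fit_window = c(48, 120),
                        amplitude_window = c(36, 60),
                        period_range = c(18, 30), goodness_min = 0.70,
                        pair = NULL, seed = 1) {
  if (is.data.frame(traces)) {
    stopifnot("id" %in% names(traces))
    zt0 <- zt0_offset(traces)
    traces <- split(traces, traces$id)
    traces <- lapply(traces, function(df) {
      biolum_trace(df$time_hours, df$value, zt0_offset = zt0)
    })
  }
  stopifnot(length(traces) >= 1, !is.null(names(traces)))
  params <- list(fit_window = fit_window, amplitude_window = amplitude_window,
                 period_range = period_range, goodness_min = goodness_min,
                 pair = pair)
  rows <- list(); excl <- list(); models <- list()
  for (id in names(traces)) {
    tr <- traces[[id]]
    fit <- tryCatch(
      fit_damped_cosine(tr, fit_window, classify_range = period_range,
                        goodness_min = goodness_min),
      error = function(e) e)
    amp <- tryCatch(peak_trough_amplitude(tr, amplitude_window),
                    error = function(e) NA_real_)
    if (inherits(fit, "error")) {
      rows[[id]] <- tibble::tibble(id = id, period = NA_real_,
                                   peak_phase_zt = NA_real_,
                                   amplitude = amp, goodness = NA_real_,
                                   is_circadian = FALSE)
      excl[[id]] <- tibble::tibble(subject = id,
                                   reason = conditionMessage(fit))
      next
    }
    models[[id]] <- fit
    rows[[id]] <- tibble::tibble(id = id, period = fit$period,
                                 peak_phase_zt = fit$peak_phase_zt,
                                 amplitude = amp, goodness = fit$goodness,
                                 is_circadian = fit$is_circadian)
    if (!fit$is_circadian) {
      excl[[id]] <- tibble::tibble(
        subject = id,
        reason = sprintf("not circadian (period %.1f h, r = %.2f)",
                         fit$period, fit$goodness))
    }
  }
  fits <- dplyr::bind_rows(rows)
  if (!is.null(meta)) fits <- dplyr::left_join(fits, meta, by = "id")
  circ <- fits[fits$is_circadian, ]
  rayleigh <- if (nrow(circ) >= 2) {
    if ("tissue" %in% names(circ)) {
      circ |>
        dplyr::group_by(.data$tissue) |>
        dplyr::filter(dplyr::n() >= 2) |>
        dplyr::group_modify(~ rayleigh_stat(.x$peak_phase_zt)) |>
        dplyr::ungroup()
    } else {
      rayleigh_stat(circ$peak_phase_zt)
    }
  } else NULL
  pair_difference <- NULL
  if (!is.null(pair) && !is.null(meta) &&
      all(c("subject", "tissue") %in% names(fits))) {
    a <- circ[circ$tissue == pair[1], c("subject", "peak_phase_zt")]
    b <- circ[circ$tissue == pair[2], c("subject", "peak_phase_zt")]
    common <- intersect(a$subject, b$subject)
    if (length(common) >= 1) {
      names(a)[2] <- "time_zt"; names(b)[2] <- "time_zt"
      pair_difference <- phase_difference(a[a$subject %in% common, ],
                                          b[b$subject %in% common, ],
                                          paired = TRUE)
    }
  }
  new_study_report("explant", params, seed, fits = fits,
                   exclusions = dplyr::bind_rows(excl), rayleigh = rayleigh,
                   pair_difference = pair_difference, models = models)
}

#' Compare intra-pregnancy synchrony between treatment groups
#'
#' Computes the per-dam Kuramoto sync series for each group (same pixel
#' pipeline as [run_inutero()]), aligns them on a common time grid, and
#' reports per-group mean and SEM trajectories plus the per-time-point
#' difference between the first two groups. Descriptive only: group-level
#' inference is out of scope here.
#'
#' @param groups named list (>= 2 entries); each entry is a named list of
#'   stacks or simulation results.
#' @param grid_dt common time grid step, hours.
#' @inheritParams run_inutero
#' @return a `study_report` with `sync` (per dam), `group_summary`
#'   (`group`, `time_hours`, `mean_r`, `sem`, `n`) and `difference`
#'   (first group minus second).
#' @export
run_treatment_compare <- function(groups, grid_dt = 1, gaussian_sigma = 1,
                                  resample_dt = 1, detrend_cutoff = 48,
                                  smooth_cutoff = 4, sync_smooth_hours = 2,
                                  seed = 1) {
  stopifnot(length(groups) >= 2, !is.null(names(groups)))
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stopf("every group needs at least one subject")
  }
  params <- list(grid_dt = grid_dt, gaussian_sigma = gaussian_sigma,
                 resample_dt = resample_dt, detrend_cutoff = detrend_cutoff,
                 smooth_cutoff = smooth_cutoff,
                 sync_smooth_hours = sync_smooth_hours)
  sync <- purrr::map_dfr(names(groups), function(g) {
    purrr::map_dfr(names(groups[[g]]), function(dam) {
      sc <- dam_sync_series(as_stack(groups[[g]][[dam]]), gaussian_sigma,
                            resample_dt, detrend_cutoff, smooth_cutoff,
                            smooth_hours = sync_smooth_hours)
      dplyr::mutate(sc, group = g, subject = dam, .before = 1)
    })
  })
  lo <- max(tapply(sync$time_hours, paste(sync$group, sync$subject), min))
  hi <- min(tapply(sync$time_hours, paste(sync$group, sync$subject), max))
  grid <- seq(lo, hi, by = grid_dt)
  aligned <- sync |>
    dplyr::group_by(.data$group, .data$subject) |>
    dplyr::reframe(r = stats::approx(.data$time_hours, .data$r, xout = grid,
                                     rule = 2)$y,
                   time_hours = grid)
  group_summary <- aligned |>
    dplyr::group_by(.data$group, .data$time_hours) |>
    dplyr::summarise(mean_r = mean(.data$r),
                     sem = stats::sd(.data$r) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  g12 <- names(groups)[1:2]
  w <- tidyr::pivot_wider(group_summary[group_summary$group %in% g12,
                                        c("group", "time_hours", "mean_r")],
                          names_from = "group", values_from = "mean_r")
  difference <- tibble::tibble(time_hours = w$time_hours,
                               difference = w[[g12[1]]] - w[[g12[2]]])
  new_study_report("treatment_compare", params, seed, sync = sync,
                   group_summary = group_summary, difference = difference)
}
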