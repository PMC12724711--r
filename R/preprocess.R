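#' Dark-count subtraction and dual-sensor summation
#'
#' Photomultiplier recordings interleave signal samples with shutter-closed
#' samples that measure only detector dark counts. For each sensor the dark
#' level is estimated locally (mean of dark-interval samples within a
#' sliding window, linearly interpolated to every timestamp, so slow dark
#' drift is tracked) and subtracted; the corrected sensors are then summed.
#' Dark-interval samples are dropped from the output, leaving a gap in the
#' timestamps.
#'
#' @param sensor_a,sensor_b traces sharing identical timestamps and `dark`
#'   masks.
#' @param window width (hours) of the local dark-estimation window.
#' @return a [biolum_trace()] of summed, dark-corrected counts.
#' @export
subtract_dark_and_sum <- function(sensor_a, sensor_b, window = 1) {
  validate_trace(sensor_a); validate_trace(sensor_b)
  if (!isTRUE(all.equal(sensor_a$time_hours, sensor_b$time_hours))) {
    stopf("sensors must share one time grid")
  }
  da <- sensor_a$dark %||% rep(FALSE, nrow(sensor_a))
  db <- sensor_b$dark %||% rep(FALSE, nrow(sensor_b))
  if (!identical(da, db)) stopf("sensors must share one dark mask")
  dark_level <- function(tr) {
    d <- tr$dark %||% rep(FALSE, nrow(tr))
    if (!any(d)) return(rep(0, nrow(tr)))
    td <- tr$time_hours[d]; xd <- tr$value[d]
    loc <- vapply(td, function(t0) mean(xd[abs(td - t0) <= window / 2]),
                  numeric(1))
    if (length(td) == 1) return(rep(loc, nrow(tr)))
    stats::approx(td, loc, xout = tr$time_hours, rule = 2)$y
  }
  corrected <- (sensor_a$value - dark_level(sensor_a)) +
    (sensor_b$value - dark_level(sensor_b))
  keep <- !da
  out <- biolum_trace(sensor_a$time_hours[keep], corrected[keep],
                      zt0_offset = zt0_offset(sensor_a),
                      meta = attr(sensor_a, "meta") %||% list())
  out
}

# exact integral of the piecewise-linear interpolant of (t, x) from a to b
# (a, b within range(t)); vectorized over a, b
pl_integral <- function(t, x, a, b) {
  cum <- c(0, cumsum(diff(t) * (utils::head(x, -1) + utils::tail(x, -1)) / 2))
  at <- function(s) {
    j <- pmin(pmax(findInterval(s, t), 1L), length(t) - 1L)
    xs <- x[j] + (x[j + 1L] - x[j]) * (s - t[j]) / (t[j + 1L] - t[j])
    cum[j] + (s - t[j]) * (x[j] + xs) / 2
  }
  at(b) - at(a)
}

#' Running-mean detrend
#'
#' Subtracts a centred moving average taken over a fixed span of *time*
#' (not a fixed number of samples), so uneven sampling is averaged without
#' bias: the window mean is the exact integral mean of the piecewise-linear
#' interpolant over `[t - window/2, t + window/2]`. A 24-h window
#' annihilates any pure 24-h periodic component and any linear trend.
#' Samples whose full window does not fit inside the record are marked
#' invalid (`valid = FALSE`, value `NA`) rather than padded: padding would
#' fabricate data at the very epochs (recording onset) analysed for rhythm
#' emergence.
#'
#' @param trace a trace spanning at least `window` hours.
#' @param window averaging span, hours.
#' @return the trace with `value` replaced by the residual and a `valid`
#'   column added.
#' @export
running_mean_detrend <- function(trace, window = 24) {
  validate_trace(trace)
  t <- trace$time_hours; x <- trace$value
  if (diff(range(t)) < window) {
    stopf("trace spans %.1f h; %g h are needed", diff(range(t)), window)
  }
  valid <- (t - window / 2) >= t[1] & (t + window / 2) <= t[length(t)]
  resid <- rep(NA_real_, length(t))
  resid[valid] <- x[valid] -
    pl_integral(t, x, t[valid] - window / 2, t[valid] + window / 2) / window
  out <- tibble::tibble(time_hours = t, value = resid, valid = valid)
  rewrap_trace(out, trace)
}

#' Sinc detrend and smooth
#'
#' The pixel-series conditioning step: a zero-lag windowed-sinc low pass at
#' `detrend_cutoff` is subtracted (removing the slow gestational trend),
#' then a second low pass at `smooth_cutoff` suppresses sample noise.
#' Requires a uniform time grid; resample first if needed.
#'
#' @param trace a trace on a uniform grid (or any data frame with
#'   `time_hours` and `value`).
#' @param detrend_cutoff,smooth_cutoff cutoff periods in hours; must
#'   satisfy `detrend_cutoff > smooth_cutoff > 2 * sampling interval`.
#' @return the trace with `value` replaced by the detrended, smoothed
#'   series.
#' @export
sinc_detrend_smooth <- function(trace, detrend_cutoff = 48, smooth_cutoff = 4) {
  validate_trace(trace)
  t <- trace$time_hours
  if (!is_uniform_grid(t)) stopf("sinc filtering requires a uniform time grid")
  dt <- stats::median(diff(t))
  if (!(detrend_cutoff > smooth_cutoff && smooth_cutoff > 2 * dt)) {
    stopf("need detrend_cutoff > smooth_cutoff > 2 * sampling interval (%g h)", dt)
  }
  det <- trace$value - sinc_lowpass(trace$value, detrend_cutoff, dt)
  out <- tibble::tibble(time_hours = t,
                        value = sinc_lowpass(det, smooth_cutoff, dt))
  rewrap_trace(out, trace)
}

#' Adjacent-frame minimization
#'
#' Replaces each frame by the pixelwise minimum of itself and the next
#' frame (the last frame is paired backward). Any artifact confined to a
#' single frame -- cosmic-ray hits, bright readout noise -- is removed
#' exactly; smooth signal is biased by at most the inter-frame change.
#'
#' @param stack an [image_stack()] with at least 2 frames.
#' @return the filtered [image_stack()].
#' @export
adjacent_frame_minimize <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- dim(stack$frames)[3]
  if (nf < 2) stopf("adjacent-frame minimization needs >= 2 frames")
  out <- stack$frames
  out[, , 1:(nf - 1)] <- pmin(stack$frames[, , 1:(nf - 1), drop = FALSE],
                              stack$frames[, , 2:nf, drop = FALSE])
  out[, , nf] <- pmin(stack$frames[, , nf], stack$frames[, , nf - 1])
  stack$frames <- out
  stack
}

#' Block frame averaging
#'
#' Averages non-overlapping blocks of `n` consecutive frames (e.g. two
#' 30-min exposures into one hourly frame); the block timestamp is the mean
#' of its members and a trailing partial block is dropped.
#'
#' @param stack an [image_stack()].
#' @param n frames per block (>= 1).
#' @return the averaged [image_stack()].
#' @export
frame_average <- function(stack, n = 2) {
  stopifnot(inherits(stack, "image_stack"))
  if (n < 1) stopf("n must be >= 1")
  n <- as.integer(n)
  if (n == 1L) return(stack)
  nf <- dim(stack$frames)[3]
  nb <- nf %/% n
  if (nb < 1) stopf("fewer than n = %d frames", n)
  shp <- dim(stack$frames)[1:2]
  frames <- array(0, dim = c(shp, nb))
  ts <- numeric(nb)
  for (b in seq_len(nb)) {
    idx <- ((b - 1L) * n + 1L):(b * n)
    frames[, , b] <- apply(stack$frames[, , idx, drop = FALSE], c(1, 2), mean)
    ts[b] <- mean(stack$timestamps[idx])
  }
  image_stack(frames, ts, roi_mask = stack$roi_mask,
              background_mask = stack$background_mask,
              zt0_offset = stack$zt0_offset, meta = stack$meta)
}

#' Background subtraction for image stacks
#'
#' Subtracts, frame by frame, the mean intensity of the background region
#' from every pixel.
#'
#' @param stack an [image_stack()] with a `background_mask`.
#' @return the corrected [image_stack()].
#' @export
background_subtract <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(stack$background_mask) || !any(stack$background_mask)) {
    stopf("stack has no background region")
  }
  for (k in seq_len(dim(stack$frames)[3])) {
    stack$frames[, , k] <- stack$frames[, , k] -
      mean(stack$frames[, , k][stack$background_mask])
  }
  stack
}

#' Total ROI photon flux per frame
#'
#' The fixed-region quantification of whole-abdomen imaging: per frame,
#' `flux = sum(ROI pixels) - n_ROI * mean(background pixels)`.
#'
#' @param stack an [image_stack()] with `roi_mask` and `background_mask`.
#' @return a [biolum_trace()] on the frame timestamps.
#' @export
roi_flux <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(stack$roi_mask) || !any(stack$roi_mask)) stopf("empty ROI")
  if (is.null(stack$background_mask) || !any(stack$background_mask)) {
    stopf("empty background region")
  }
  n_roi <- sum(stack$roi_mask)
  flux <- vapply(seq_len(dim(stack$frames)[3]), function(k) {
    f <- stack$frames[, , k]
    sum(f[stack$roi_mask]) - n_roi * mean(f[stack$background_mask])
  }, numeric(1))
  biolum_trace(stack$timestamps, flux, zt0_offset = stack$zt0_offset,
               meta = stack$meta)
}

#' Extract per-pixel time series
#'
#' Spatially smooths each frame with an isotropic Gaussian (`sigma = 0` is
#' the identity) and returns one time series per ROI pixel on the shared
#' frame time grid, in long (tidy) form. Apply after
#' [adjacent_frame_minimize()], [frame_average()] and
#' [background_subtract()].
#'
#' @param stack an [image_stack()] with an `roi_mask`.
#' @param gaussian_sigma Gaussian SD in pixels (>= 0).
#' @return a tibble with columns `pixel`, `row`, `col`, `time_hours`,
#'   `value`; attribute `zt0_offset` is carried over.
#' @export
extract_pixel_series <- function(stack, gaussian_sigma = 1) {
  stopifnot(inherits(stack, "image_stack"))
  if (gaussian_sigma < 0) stopf("gaussian_sigma must be >= 0")
  if (is.null(stack$roi_mask) || !any(stack$roi_mask)) stopf("empty ROI")
  idx <- which(stack$roi_mask, arr.ind = TRUE)
  nf <- dim(stack$frames)[3]
  vals <- matrix(0, nrow(idx), nf)
  for (k in seq_len(nf)) {
    f <- stack$frames[, , k]
    if (gaussian_sigma > 0) f <- EBImage::gblur(f, sigma = gaussian_sigma)
    vals[, k] <- f[idx]
  }
  out <- tibble::tibble(
    pixel = rep(sprintf("px_%d_%d", idx[, 1], idx[, 2]), each = nf),
    row = rep(idx[, 1], each = nf),
    col = rep(idx[, 2], each = nf),
    time_hours = rep(stack$timestamps, nrow(idx)),
    value = as.vector(t(vals)))
  attr(out, "zt0_offset") <- stack$zt0_offset
  out
}
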