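#' Wrap clock times onto the Zeitgeber circle
#'
#' @param x numeric hours.
#' @param modulus circle length in hours (24 for Zeitgeber Time).
#' @return `wrap_zt()` maps to `[0, modulus)`; `wrap_half()` maps to
#'   `(-modulus/2, modulus/2]`, the convention used for signed phase
#'   differences.
#' @export
wrap_zt <- function(x, modulus = 24) {
  out <- x %% modulus
  out[out == modulus] <- 0
  out
}

#' @rdname wrap_zt
#' @export
wrap_half <- function(x, modulus = 24) {
  modulus / 2 - ((modulus / 2 - x) %% modulus)
}

# circular mean of hour-valued times on a `modulus`-hour circle
circ_mean_hours <- function(x, modulus = 24, w = NULL) {
  th <- 2 * pi * x / modulus
  if (is.null(w)) w <- rep(1, length(x))
  w <- w / sum(w)
  wrap_zt(atan2(sum(w * sin(th)), sum(w * cos(th))) * modulus / (2 * pi), modulus)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_uniform_grid <- function(t, rel_tol = 1e-6) {
  if (length(t) < 3) return(TRUE)
  d <- diff(t)
  (max(d) - min(d)) <= rel_tol * stats::median(d)
}

# Hamming-windowed sinc low-pass kernel. `cutoff` and `dt` in hours.
# Kernel sums to exactly 1 so DC gain is 1 (constants pass unchanged).
sinc_kernel <- function(cutoff, dt, span = 2 * cutoff) {
  if (cutoff <= 2 * dt) {
    stopf("low-pass cutoff (%g h) must exceed twice the sampling interval (%g h)",
          cutoff, dt)
  }
  M <- max(1L, as.integer(floor(span / dt / 2)))
  k <- -M:M
  x <- 2 * (dt / cutoff) * k
  h <- ifelse(x == 0, 1, sin(pi * x) / (pi * x)) * 2 * (dt / cutoff)
  h <- h * (0.54 + 0.46 * cos(pi * k / M))
  h / sum(h)
}

#' Zero-lag windowed-sinc low-pass filter
#'
#' Convolves a uniformly sampled series with a Hamming-windowed sinc kernel
#' whose -6 dB point sits at `1/cutoff` cycles per hour. The kernel is
#' symmetric (linear phase, zero lag) and edges are handled by reflection
#' padding, so a constant series is returned unchanged.
#'
#' @param x numeric series on a uniform grid.
#' @param cutoff cutoff period in hours.
#' @param dt sampling interval in hours.
#' @param span kernel support in hours (default twice the cutoff, truncated
#'   to the series length when the record is shorter).
#' @return filtered series, same length as `x`.
#' @export
sinc_lowpass <- function(x, cutoff, dt, span = 2 * cutoff) {
  n <- length(x)
  span <- min(span, (n - 1) * dt)
  h <- sinc_kernel(cutoff, dt, span)
  M <- (length(h) - 1L) / 2L
  if (M >= n) stopf("series too short (%d samples) for the filter support", n)
  # reflect about the end points
  xp <- c(x[(M + 1L):2L], x, x[(n - 1L):(n - M)])
  stats::convolve(xp, rev(h), type = "filter")
}

# resample a possibly uneven series to a uniform grid by linear interpolation
resample_uniform <- function(time_hours, value, dt) {
  grid <- seq(min(time_hours), max(time_hours), by = dt)
  v <- stats::approx(time_hours, value, xout = grid)$y
  tibble::tibble(time_hours = grid, value = v)
}

pkg_version <- function() as.character(utils::packageVersion("lucisync"))
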