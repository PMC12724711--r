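#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a bioluminescence trace
#'
#' Raw or detrended counts against time, with the prior dark phases
#' (ZT12-24) shaded.
#'
#' @param trace a trace.
#' @param shade_nights shade ZT12-24 bands.
#' @return a ggplot.
#' @export
plot_trace <- function(trace, shade_nights = TRUE) {
  trace <- drop_invalid(trace)
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$time_hours, .data$value))
  if (shade_nights) {
    zt0 <- zt0_offset(trace)
    t0 <- min(trace$time_hours); t1 <- max(trace$time_hours)
    starts <- seq(zt0 + 12 + 24 * floor((t0 - zt0 - 12) / 24), t1, by = 24)
    bands <- tibble::tibble(xmin = pmax(starts, t0),
                            xmax = pmin(starts + 12, t1))
    bands <- bands[bands$xmax > bands$xmin, ]
    if (nrow(bands)) {
      p <- p + ggplot2::geom_rect(
        data = bands,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, fill = "grey85", alpha = 0.6)
    }
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h from recording start)",
                  y = "Bioluminescence") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_trace autoplot method for traces.
#' @param object,... autoplot arguments.
#' @export
autoplot.biolum_trace <- function(object, ...) plot_trace(object, ...)

#' Plot a damped-cosine fit over its data
#'
#' @param object a [fit_damped_cosine()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.damped_cosine_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(.data$time_hours, .data$value)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5)
  if (!is.null(object$fitted)) {
    p <- p + ggplot2::geom_line(data = object$fitted,
                                ggplot2::aes(y = .data$fitted),
                                colour = "firebrick")
  }
  p + ggplot2::labs(x = "Time (h)", y = "Bioluminescence",
                    subtitle = sprintf("T = %.2f h, peak ZT %.1f, r = %.2f",
                                       object$period, object$peak_phase_zt,
                                       object$goodness)) +
    ggplot2::theme_minimal()
}

#' Plot synchrony time courses
#'
#' One Kuramoto order-parameter trajectory per subject (or the group
#' mean with a SEM ribbon for a treatment-comparison report).
#'
#' @param sync tibble from [sync_timecourse()] or a `study_report`.
#' @return a ggplot.
#' @export
plot_sync <- function(sync) {
  if (inherits(sync, "study_report")) {
    if (!is.null(sync$group_summary)) {
      return(
        ggplot2::ggplot(sync$group_summary,
                        ggplot2::aes(.data$time_hours, .data$mean_r,
                                     colour = .data$group,
                                     fill = .data$group)) +
          ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_r - .data$sem,
                                            ymax = .data$mean_r + .data$sem),
                               alpha = 0.2, colour = NA) +
          ggplot2::geom_line() +
          ggplot2::coord_cartesian(ylim = c(0, 1)) +
          ggplot2::labs(x = "Time (h)", y = "Sync index (Kuramoto r)") +
          ggplot2::theme_minimal())
    }
    sync <- sync$sync
  }
  aes <- if ("subject" %in% names(sync)) {
    ggplot2::aes(.data$time_hours, .data$r, colour = .data$subject)
  } else {
    ggplot2::aes(.data$time_hours, .data$r)
  }
  ggplot2::ggplot(sync, aes) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (h)", y = "Sync index (Kuramoto r)") +
    ggplot2::theme_minimal()
}

#' Circular plot of peak times
#'
#' Daily peak times on the 24-h clock face with the resultant vector of
#' the Rayleigh statistic.
#'
#' @param peaks tibble with `time_zt` (hours).
#' @return a ggplot.
#' @export
plot_rayleigh <- function(peaks) {
  x <- if (is.data.frame(peaks)) peaks$time_zt else as.numeric(peaks)
  rs <- rayleigh_stat(x)
  pts <- tibble::tibble(time_zt = wrap_zt(x), r = 1)
  arrow_df <- tibble::tibble(x = rs$mean_direction, y = rs$R)
  ggplot2::ggplot(pts, ggplot2::aes(.data$time_zt, .data$r)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_segment(data = arrow_df,
                          ggplot2::aes(x = .data$x, xend = .data$x,
                                       y = 0, yend = .data$y),
                          colour = "firebrick", linewidth = 1) +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = seq(0, 18, by = 6)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Zeitgeber Time (h)", y = NULL,
                  subtitle = sprintf("R = %.2f, mean ZT %.1f, n = %d",
                                     rs$R, rs$mean_direction, rs$n)) +
    ggplot2::theme_minimal()
}
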