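#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a damped-cosine fit
#'
#' @param x a [fit_damped_cosine()] result.
#' @param ... unused.
#' @return tibble with one row per model parameter (`term`, `estimate`).
#' @export
tidy.damped_cosine_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mesor", "amplitude", "damping_rate", "period", "peak_phase_zt"),
    estimate = c(x$mesor, x$amplitude, x$damping_rate, x$period,
                 x$peak_phase_zt))
}

#' One-row summary of a damped-cosine fit
#'
#' The rhythm-fit record: period, ZT peak phase, amplitude, damping,
#' mesor, goodness of fit and the circadian classification.
#'
#' @inheritParams tidy.damped_cosine_fit
#' @export
glance.damped_cosine_fit <- function(x, ...) {
  tibble::tibble(period = x$period, peak_phase_zt = x$peak_phase_zt,
                 amplitude = x$amplitude, damping_rate = x$damping_rate,
                 mesor = x$mesor, goodness = x$goodness,
                 p_value = NA_real_, is_circadian = x$is_circadian,
                 method = "damped_cosine", n = x$n,
                 converged = x$converged)
}

#' Tidy a study report
#'
#' @param x a `study_report`.
#' @param ... unused.
#' @return the per-subject fit table.
#' @export
tidy.study_report <- function(x, ...) x$fits

#' @export
glance.study_report <- function(x, ...) {
  tibble::tibble(kind = x$kind,
                 n_subjects = nrow(x$fits %||% data.frame()),
                 n_circadian = sum((x$fits %||% data.frame())$is_circadian,
                                   na.rm = TRUE),
                 n_excluded = nrow(x$exclusions %||% data.frame()),
                 config_hash = x$config_hash, version = x$version)
}
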