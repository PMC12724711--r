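#' Bioluminescence trace
#'
#' A trace is a tibble with a `time_hours` column (hours from recording
#' start, strictly increasing, possibly unevenly spaced) and a `value`
#' column (counts or photons/s). Optional columns: `dark` (logical, TRUE
#' for samples recorded with the shutter closed) and `valid` (logical,
#' FALSE for samples invalidated by an edge-sensitive filter). Two
#' attributes travel with the trace: `zt0_offset`, the hours from
#' recording start to the reference lights-on (so the Zeitgeber Time of a
#' sample is `(time_hours - zt0_offset) %% 24`), and `meta`, a free-form
#' list of labels (subject, tissue, treatment).
#'
#' @param time_hours strictly increasing numeric vector, hours.
#' @param value finite numeric vector, same length.
#' @param dark optional logical vector, same length.
#' @param zt0_offset hours from recording start to the reference lights-on.
#' @param meta list of labels.
#' @return a `biolum_trace` tibble.
#' @export
biolum_trace <- function(time_hours, value, dark = NULL, zt0_offset = 0,
                         meta = list()) {
  df <- tibble::tibble(time_hours = as.numeric(time_hours),
                       value = as.numeric(value))
  if (!is.null(dark)) df$dark <- as.logical(dark)
  validate_trace(df)
  attr(df, "zt0_offset") <- zt0_offset
  attr(df, "meta") <- meta
  class(df) <- c("biolum_trace", class(df))
  df
}

validate_trace <- function(df) {
  if (!all(c("time_hours", "value") %in% names(df))) {
    stopf("a trace needs `time_hours` and `value` columns; missing: %s",
          paste(setdiff(c("time_hours", "value"), names(df)), collapse = ", "))
  }
  bad <- which(diff(df$time_hours) <= 0)
  if (length(bad)) {
    stopf("timestamps must be strictly increasing; first violation at row %d",
          bad[1] + 1L)
  }
  invalid_ok <- if ("valid" %in% names(df)) !df$valid else rep(FALSE, nrow(df))
  nf <- which(!is.finite(df$value) & !invalid_ok)
  if (length(nf)) stopf("non-finite value at row %d", nf[1])
  if ("dark" %in% names(df) && length(df$dark) != nrow(df)) {
    stopf("dark mask length differs from the number of samples")
  }
  invisible(df)
}

# carry trace attributes through a transformation of the data columns
rewrap_trace <- function(df, template) {
  attr(df, "zt0_offset") <- zt0_offset(template)
  attr(df, "meta") <- attr(template, "meta") %||% list()
  if (!inherits(df, "biolum_trace")) class(df) <- c("biolum_trace", class(df))
  df
}

#' @rdname biolum_trace
#' @param trace a trace (any data frame with the trace columns).
#' @export
zt0_offset <- function(trace) attr(trace, "zt0_offset") %||% 0

#' Zeitgeber Time of each sample of a trace
#' @inheritParams zt0_offset
#' @return numeric vector in `[0, 24)`.
#' @export
trace_zt <- function(trace) wrap_zt(trace$time_hours - zt0_offset(trace))

#' Read and write bioluminescence traces
#'
#' Traces are stored as delimited text with columns `time_hours`, `value`,
#' and optionally `is_dark_interval` (0/1). `zt0_offset` is kept in a
#' commented header line so that a round trip preserves the ZT reference.
#' Files with missing columns, duplicated or non-increasing timestamps are
#' rejected with the offending row named.
#'
#' @param path file path.
#' @return `read_trace()` returns a [biolum_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stopf("no such trace file: %s", path)
  first <- readLines(path, n = 1L)
  zt0 <- 0
  if (grepl("^#\\s*zt0_offset\\s*=", first)) {
    zt0 <- as.numeric(sub("^#\\s*zt0_offset\\s*=\\s*", "", first))
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("time_hours", "value") %in% names(df))) {
    stopf("%s: required columns time_hours, value; found: %s", path,
          paste(names(df), collapse = ", "))
  }
  dup <- which(duplicated(df$time_hours))
  if (length(dup)) stopf("%s: duplicated timestamp at row %d", path, dup[1])
  biolum_trace(df$time_hours, df$value,
               dark = if ("is_dark_interval" %in% names(df)) df$is_dark_interval > 0,
               zt0_offset = zt0)
}

#' @rdname read_trace
#' @param trace a trace.
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  out <- tibble::tibble(time_hours = trace$time_hours, value = trace$value)
  if ("dark" %in% names(trace)) out$is_dark_interval <- as.integer(trace$dark)
  writeLines(sprintf("# zt0_offset=%.17g", zt0_offset(trace)), path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
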