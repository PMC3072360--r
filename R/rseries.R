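#' Roundness order-parameter time series
#'
#' Container for an R(t) series: positive roundness values sampled at a
#' uniform interval `dt` (seconds). The canonical recording in this package
#' is 900 points at one frame per 2 s (30 minutes).
#'
#' @param values numeric vector of roundness values, all > 0.
#' @param dt sampling interval in seconds (> 0).
#' @param cell_id character label for the cell.
#' @param state_label one of `"idling"`, `"treadmilling"`, `"translocating"`,
#'   `"transition"`, `"unknown"`.
#' @return an object of class `r_series`.
#' @export
r_series <- function(values, dt = 2, cell_id = "cell", state_label = "unknown") {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0))
    md_error("morphodyn_domain", "R values must be positive and finite")
  if (!is.numeric(dt) || dt <= 0) md_error("morphodyn_domain", "dt must be > 0")
  state_label <- match.arg(state_label,
    c("idling", "treadmilling", "translocating", "transition", "unknown"))
  structure(list(values = values, dt = dt, n = length(values),
                 cell_id = cell_id, state_label = state_label),
            class = "r_series")
}

#' @export
print.r_series <- function(x, ...) {
  cat(sprintf("<r_series> %s [%s]: n = %d, dt = %gs, mean R = %.4f, SD = %.4f\n",
              x$cell_id, x$state_label, x$n, x$dt, mean(x$values), stats::sd(x$values)))
  invisible(x)
}

# Coerce numeric/r_series input for the measure functions.
as_r_values <- function(series) {
  if (inherits(series, "r_series")) series$values else as.numeric(series)
}

series_dt <- function(series, dt = NULL) {
  if (!is.null(dt)) return(dt)
  if (inherits(series, "r_series")) series$dt else 2
}

#' Read / write R(t) series as two-column CSV
#'
#' The exchange format is a CSV with a one-line header `time_s,R`.
#'
#' @param path file path.
#' @param series an [r_series()].
#' @param ... metadata passed to [r_series()] on read.
#' @return `read_r_series()` returns an [r_series()]; `write_r_series()`
#'   returns `path` invisibly.
#' @export
read_r_series <- function(path, ...) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "R") %in% names(d)))
    md_error("morphodyn_io", "expected columns time_s and R")
  dt <- if (nrow(d) > 1) stats::median(diff(d$time_s)) else 2
  r_series(d$R, dt = dt, ...)
}

#' @rdname read_r_series
#' @export
write_r_series <- function(series, path) {
  stopifnot(inherits(series, "r_series"))
  d <- data.frame(time_s = (seq_len(series$n) - 1) * series$dt, R = series$values)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
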