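#' Construct a uniformly sampled time-series tibble
#'
#' All channels in respox are plain tibbles with a `time` column (seconds) and
#' a `value` column, so they compose directly with dplyr/tidyr verbs. The
#' sampling rate is implicit in the time grid and recovered with [ts_rate()].
#'
#' @param values Numeric vector of samples.
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param units Optional unit string, stored as the `"units"` attribute.
#' @return A tibble with columns `time` and `value`.
#' @export
#' @examples
#' ts <- ts_new(sin(2 * pi * 2 * (0:99) / 100), rate = 100)
#' ts_rate(ts)
ts_new <- function(values, rate, t0 = 0, units = NULL) {
  stopifnot(is.numeric(values), length(values) > 0L)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  out <- tibble::tibble(
    time = t0 + (seq_along(values) - 1) / rate,
    value = as.numeric(values)
  )
  if (!is.null(units)) attr(out, "units") <- units
  out
}

#' Sampling rate of a time-series tibble
#'
#' @param ts A tibble with a `time` column on a uniform grid.
#' @return Sampling rate in Hz.
#' @export
ts_rate <- function(ts) {
  tm <- ts_time(ts)
  if (length(tm) < 2L) stop("need at least two samples to infer a rate", call. = FALSE)
  dt <- diff(tm)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop("time grid is not uniform", call. = FALSE)
  }
  1 / stats::median(dt)
}

ts_time <- function(ts) {
  if (!is.data.frame(ts) || !"time" %in% names(ts)) {
    stop("expected a data frame with a `time` column", call. = FALSE)
  }
  ts[["time"]]
}

ts_values <- function(ts, col = "value") {
  if (!is.data.frame(ts) || !col %in% names(ts)) {
    stop(sprintf("expected a data frame with a `%s` column", col), call. = FALSE)
  }
  v <- ts[[col]]
  if (!all(is.finite(v))) stop("time series contains non-finite values", call. = FALSE)
  v
}

ts_like <- function(ts, values, units = NULL) {
  out <- tibble::tibble(time = ts_time(ts)[seq_along(values)], value = values)
  if (!is.null(units)) attr(out, "units") <- units
  out
}

#' Export a time series to CSV
#'
#' @param ts Time-series tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
ts_write_csv <- function(ts, path) {
  utils::write.csv(as.data.frame(ts[c("time", "value")]), path, row.names = FALSE)
  invisible(path)
}
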