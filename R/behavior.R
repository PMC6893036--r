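#' Binarize treadmill velocity into locomotion
#'
#' Low-passes the velocity signal (10 Hz, 5th-order zero-phase Butterworth),
#' differentiates it to acceleration by central differences, and marks a
#' sample as locomotion when the absolute acceleration reaches the threshold
#' `a_c` (inclusive).
#'
#' @param velocity Time-series tibble of treadmill velocity (cm/s).
#' @param lp_cutoff Low-pass cutoff applied to velocity, Hz.
#' @param a_c Acceleration threshold, cm/s^2.
#' @param order Butterworth order of the velocity low-pass.
#' @return A tibble with columns `time` and `delta` (0/1).
#' @export
binarize_locomotion <- function(velocity, lp_cutoff = 10, a_c = 3, order = 5) {
  rate <- ts_rate(velocity) # errors on non-uniform sampling
  if (rate <= 2 * lp_cutoff) {
    stop("velocity rate must exceed twice the low-pass cutoff", call. = FALSE)
  }
  v <- butter_zp(ts_values(velocity), rate, lp_cutoff, order, "low")
  n <- length(v)
  a <- numeric(n)
  a[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * rate / 2
  a[1] <- (v[2] - v[1]) * rate
  a[n] <- (v[n] - v[n - 1]) * rate
  tibble::tibble(time = ts_time(velocity), delta = as.integer(abs(a) >= a_c))
}

delta_runs <- function(delta) {
  d <- delta[["delta"]]
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(
    start = starts[r$values == 1L],
    end = ends[r$values == 1L]
  )
}

merge_runs <- function(runs, rate, merge_gap) {
  if (nrow(runs) < 2L || merge_gap <= 0) {
    return(runs)
  }
  gap <- (runs$start[-1] - runs$end[-nrow(runs)] - 1L) / rate
  grp <- cumsum(c(0L, as.integer(gap >= merge_gap)))
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(runs, .grp = grp), .data$.grp),
    start = min(.data$start), end = max(.data$end), .groups = "drop"
  )
  out[c("start", "end")]
}

#' Locomotion-evoked events
#'
#' Identifies locomotion bouts usable for event-triggered analyses: runs of
#' `delta == 1` (gaps shorter than `merge_gap` bridged) that are preceded by
#' at least `min_pre_rest` of stillness and last at least `min_loco`. For
#' oxygen analyses `min_loco` is conventionally raised to 10 s.
#'
#' @param delta Binarized locomotion tibble from [binarize_locomotion()].
#' @param min_pre_rest Required still period before onset, s.
#' @param min_loco Required bout duration, s.
#' @param merge_gap Gaps between runs shorter than this are merged, s.
#' @return Event tibble with columns `onset`, `offset`, `kind`, `duration`.
#' @export
segment_events <- function(delta, min_pre_rest = 3, min_loco = 5, merge_gap = 0.5) {
  stopifnot(merge_gap >= 0)
  rate <- ts_rate(delta)
  tm <- ts_time(delta)
  runs <- merge_runs(delta_runs(delta), rate, merge_gap)
  empty <- tibble::tibble(
    onset = numeric(), offset = numeric(),
    kind = character(), duration = numeric()
  )
  if (nrow(runs) == 0L) {
    return(empty)
  }
  onset <- tm[runs$start]
  offset <- tm[runs$end] + 1 / rate
  dur <- offset - onset
  pre_quiet <- c(onset[1] - tm[1], onset[-1] - offset[-length(offset)])
  keep <- dur >= min_loco & pre_quiet >= min_pre_rest
  tibble::tibble(
    onset = onset[keep], offset = offset[keep],
    kind = "locomotion", duration = dur[keep]
  )
}

#' Resting periods
#'
#' Rest intervals start `post_gap` seconds after each locomotion run ends and
#' extend to the next run onset (session boundaries count as rest
#' boundaries). Only intervals strictly longer than `min_dur` are kept; for
#' resting cross-correlation analyses `min_dur` is conventionally raised to
#' 30 s.
#'
#' @param delta Binarized locomotion tibble.
#' @param post_gap Buffer after each locomotion run, s.
#' @param min_dur Minimum retained rest duration, s (strict).
#' @param merge_gap Run-merging gap, as in [segment_events()].
#' @return Event tibble with columns `onset`, `offset`, `kind`, `duration`.
#' @export
rest_periods <- function(delta, post_gap = 4, min_dur = 10, merge_gap = 0.5) {
  rate <- ts_rate(delta)
  tm <- ts_time(delta)
  t_end <- tm[length(tm)] + 1 / rate
  runs <- merge_runs(delta_runs(delta), rate, merge_gap)
  if (nrow(runs) == 0L) {
    starts <- tm[1]
    ends <- t_end
  } else {
    run_on <- tm[runs$start]
    run_off <- tm[runs$end] + 1 / rate
    starts <- c(tm[1], run_off + post_gap)
    ends <- c(run_on, t_end)
  }
  dur <- ends - starts
  keep <- dur > min_dur
  tibble::tibble(
    onset = starts[keep], offset = ends[keep],
    kind = "rest", duration = dur[keep]
  )
}
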