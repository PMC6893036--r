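#' Two-point polarographic electrode calibration
#'
#' Bundles the pre- and post-session current readings of a Clark-type oxygen
#' electrode in zero-oxygen and air-saturated saline, used by
#' [drift_correct()] to convert current to mmHg while compensating linear
#' sensor drift.
#'
#' @param pre_zero,pre_sat Current readings at 0% O2 and in air-saturated
#'   saline before the session.
#' @param post_zero,post_sat The same readings after the session.
#' @param t_pre,t_post Timestamps (s) of the two calibrations; the recording
#'   must lie between them.
#' @param sat_po2 Oxygen tension of air-saturated saline in mmHg. The default
#'   corresponds to water-vapor-saturated air at 37 degrees C,
#'   (760 - 47) x 0.2095.
#' @param temperature Bath temperature in degrees C (metadata only).
#' @return An object of class `electrode_cal`.
#' @export
electrode_calibration <- function(pre_zero, pre_sat, post_zero, post_sat,
                                  t_pre, t_post, sat_po2 = 149.4,
                                  temperature = 37) {
  if (pre_sat <= pre_zero || post_sat <= post_zero) {
    stop("saturated reading must exceed zero reading", call. = FALSE)
  }
  if (t_post <= t_pre) stop("post-calibration must follow pre-calibration", call. = FALSE)
  structure(
    list(
      pre_zero = pre_zero, pre_sat = pre_sat,
      post_zero = post_zero, post_sat = post_sat,
      t_pre = t_pre, t_post = t_post,
      sat_po2 = sat_po2, temperature = temperature
    ),
    class = "electrode_cal"
  )
}

#' Drift-corrected current-to-mmHg conversion
#'
#' Converts a raw electrode current trace to oxygen tension by linearly
#' interpolating the zero and span of the two-point calibration between the
#' pre- and post-session calibrations, so slow sensitivity drift (a few
#' percent per hour) is removed sample by sample.
#'
#' @param raw Time-series tibble of electrode current.
#' @param cal An [electrode_calibration()] object.
#' @return Time-series tibble in mmHg.
#' @export
drift_correct <- function(raw, cal) {
  stopifnot(inherits(cal, "electrode_cal"))
  tm <- ts_time(raw)
  v <- ts_values(raw)
  f <- (tm - cal$t_pre) / (cal$t_post - cal$t_pre)
  zero_t <- cal$pre_zero + f * (cal$post_zero - cal$pre_zero)
  sat_t <- cal$pre_sat + f * (cal$post_sat - cal$pre_sat)
  span <- sat_t - zero_t
  if (any(span <= 0)) {
    stop("interpolated calibration span is non-positive inside the record",
      call. = FALSE
    )
  }
  ts_like(raw, (v - zero_t) / span * cal$sat_po2, units = "mmHg")
}

#' Zero-phase low-pass filtering and downsampling
#'
#' Applies a zero-phase Butterworth low-pass of the requested order and then
#' resamples to `out_rate`. When the cutoff leaves power above the output
#' Nyquist, an additional anti-alias guard filter is applied before
#' decimation.
#'
#' @param ts Time-series tibble.
#' @param cutoff Low-pass cutoff in Hz (must be below the input Nyquist).
#' @param order Butterworth order.
#' @param out_rate Output sampling rate in Hz (defaults to the input rate).
#' @return Time-series tibble at `out_rate`.
#' @export
#' @examples
#' x <- ts_new(rnorm(3000), rate = 1000)
#' y <- lowpass_downsample(x, cutoff = 1, order = 5, out_rate = 30)
lowpass_downsample <- function(ts, cutoff, order = 5, out_rate = NULL) {
  rate <- ts_rate(ts)
  if (is.null(out_rate)) out_rate <- rate
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  if (out_rate > rate) stop("out_rate must not exceed the input rate", call. = FALSE)
  v <- butter_zp(ts_values(ts), rate, cutoff, order, "low")
  if (out_rate < rate && cutoff > 0.4 * out_rate) {
    v <- butter_zp(v, rate, 0.45 * out_rate, 8, "low")
  }
  tm <- ts_time(ts)
  if (out_rate == rate) {
    return(ts_like(ts, v, units = attr(ts, "units")))
  }
  step <- rate / out_rate
  if (abs(step - round(step)) < 1e-9) {
    idx <- seq(1L, length(v), by = round(step))
    out <- tibble::tibble(time = tm[idx], value = v[idx])
  } else {
    new_t <- seq(tm[1], tm[length(tm)], by = 1 / out_rate)
    out <- tibble::tibble(time = new_t, value = stats::approx(tm, v, new_t)$y)
  }
  attr(out, "units") <- attr(ts, "units")
  out
}

#' Zero-phase band-pass (or low-pass) filtering
#'
#' @param ts Time-series tibble.
#' @param lo,hi Band edges in Hz; `lo = 0` gives a pure low-pass at `hi`.
#' @param design `"butterworth"` (default, order `order`) or `"bessel"`.
#' @param order Filter order.
#' @return Filtered time-series tibble at the input rate.
#' @export
bandpass <- function(ts, lo, hi, design = c("butterworth", "bessel"), order = 5) {
  design <- match.arg(design)
  rate <- ts_rate(ts)
  if (lo < 0 || hi <= lo || hi >= rate / 2) {
    stop("need 0 <= lo < hi < rate/2", call. = FALSE)
  }
  x <- ts_values(ts)
  v <- if (design == "bessel") {
    if (lo > 0) stop("bessel design is supported for low-pass only", call. = FALSE)
    bessel_zp(x, rate, hi, order = min(order, 4))
  } else if (lo == 0) {
    butter_zp(x, rate, hi, order, "low")
  } else {
    butter_zp(x, rate, c(lo, hi), order, "pass")
  }
  ts_like(ts, v, units = attr(ts, "units"))
}
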