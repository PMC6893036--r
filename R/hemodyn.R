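# Reflectance-based CBV metrics, modified Beer-Lambert spectroscopy, and
# event-triggered averaging.

#' Reflectance stack container
#'
#' Holds per-wavelength reflectance frame series (time x pixel matrices) at a
#' common frame rate, with named region-of-interest pixel masks.
#'
#' @param frames Named list of time x pixel matrices; names are wavelengths
#'   in nm (e.g. `"530"`, `"470"`).
#' @param rate Frame rate, Hz.
#' @param t0 Time of the first frame, s.
#' @param roi_masks Named list of pixel index vectors; defaults to an
#'   `"all"` mask over every pixel.
#' @return An object of class `ox_reflectance`.
#' @export
reflectance_stack <- function(frames, rate, t0 = 0, roi_masks = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1, !is.null(names(frames)))
  if (anyDuplicated(names(frames))) stop("wavelengths must be distinct", call. = FALSE)
  npx <- unique(vapply(frames, ncol, integer(1)))
  nt <- unique(vapply(frames, nrow, integer(1)))
  if (length(npx) != 1L || length(nt) != 1L) {
    stop("all wavelengths must share frame dimensions", call. = FALSE)
  }
  if (any(vapply(frames, function(f) any(f <= 0), logical(1)))) {
    stop("reflectance values must be positive", call. = FALSE)
  }
  if (is.null(roi_masks)) roi_masks <- list(all = seq_len(npx))
  structure(
    list(frames = frames, rate = rate, t0 = t0, roi_masks = roi_masks),
    class = "ox_reflectance"
  )
}

#' @export
print.ox_reflectance <- function(x, ...) {
  cat(sprintf(
    "<ox_reflectance> %s nm | %d frames x %d pixels @ %g Hz | ROIs: %s\n",
    paste(names(x$frames), collapse = "/"),
    nrow(x$frames[[1]]), ncol(x$frames[[1]]), x$rate,
    paste(names(x$roi_masks), collapse = ", ")
  ))
  invisible(x)
}

#' Fractional reflectance change in a region of interest
#'
#' ROI-mean reflectance relative to its mean over a baseline interval,
#' expressed in percent (`(R/R0 - 1) x 100`). At 530 nm (hemoglobin
#' isosbestic point) this is the standard intrinsic-signal blood-volume
#' readout: darkening (negative values) means dilation.
#'
#' @param stack An [reflectance_stack()] object.
#' @param roi ROI name.
#' @param baseline Two-element time interval used as baseline, s.
#' @param wavelength Which wavelength to use (default the first).
#' @return Time-series tibble of percent reflectance change.
#' @export
delta_r <- function(stack, roi = "all", baseline = NULL, wavelength = NULL) {
  stopifnot(inherits(stack, "ox_reflectance"))
  wl <- wavelength %||% names(stack$frames)[1]
  px <- stack$roi_masks[[roi]]
  if (is.null(px) || length(px) == 0L) stop("empty or unknown ROI", call. = FALSE)
  f <- stack$frames[[as.character(wl)]]
  tm <- stack$t0 + (seq_len(nrow(f)) - 1) / stack$rate
  v <- rowMeans(f[, px, drop = FALSE])
  if (is.null(baseline)) baseline <- c(tm[1], tm[min(length(tm), max(2, round(0.1 * length(tm))))])
  sel <- tm >= baseline[1] & tm <= baseline[2]
  if (!any(sel)) stop("baseline interval outside the record", call. = FALSE)
  out <- tibble::tibble(time = tm, value = (v / mean(v[sel]) - 1) * 100)
  attr(out, "units") <- "%"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default extinction/pathlength table for hemoglobin spectroscopy
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin and effective
#' optical pathlengths at the LED wavelengths used for intrinsic-signal
#' spectroscopy. These are configuration, not constants: pass an edited
#' tibble of the same shape to use probe- or preparation-specific values.
#' Extinction coefficients are in 1/(cm M); pathlengths in cm (Monte-Carlo
#' derived, wavelength dependent).
#'
#' @return Tibble with columns `wavelength`, `eps_hbo`, `eps_hbr`,
#'   `pathlength`.
#' @export
pathlength_table <- function() {
  tibble::tibble(
    wavelength = c(470, 530, 660),
    eps_hbo = c(33209.2, 39036.7, 319.6),
    eps_hbr = c(16156.4, 39036.7, 3226.6),
    pathlength = c(0.056, 0.037, 0.30)
  )
}

bl_coef_matrix <- function(table, wavelengths) {
  rows <- match(as.numeric(wavelengths), table$wavelength)
  if (anyNA(rows)) {
    stop(
      sprintf(
        "no extinction entry for wavelength(s) %s",
        paste(wavelengths[is.na(rows)], collapse = ", ")
      ),
      call. = FALSE
    )
  }
  # DeltaA(lambda) = X(lambda) * (eps_hbo dHbO + eps_hbr dHbR), dHb in uM
  m <- cbind(
    table$eps_hbo[rows] * table$pathlength[rows],
    table$eps_hbr[rows] * table$pathlength[rows]
  ) / 1e6
  rownames(m) <- as.character(wavelengths)
  m
}

#' Forward modified Beer-Lambert map
#'
#' Converts oxy/deoxyhemoglobin concentration changes into percent
#' reflectance changes per wavelength: `R/R0 = exp(-DeltaA)` with
#' `DeltaA(lambda) = X(lambda) (eps_HbO dHbO + eps_HbR dHbR)`.
#'
#' @param hemo Tibble with columns `time`, `dHbO`, `dHbR` (uM).
#' @param wavelengths Wavelengths to synthesize, nm.
#' @param table Extinction/pathlength table, see [pathlength_table()].
#' @return Tibble with `time` and one percent-change column per wavelength.
#' @export
beer_lambert_forward <- function(hemo, wavelengths = c(530, 470),
                                 table = pathlength_table()) {
  m <- bl_coef_matrix(table, wavelengths)
  da <- cbind(hemo$dHbO, hemo$dHbR) %*% t(m)
  out <- tibble::as_tibble(as.data.frame((exp(-da) - 1) * 100))
  names(out) <- as.character(wavelengths)
  dplyr::bind_cols(tibble::tibble(time = hemo$time), out)
}

#' Invert the modified Beer-Lambert law
#'
#' Solves per-sample attenuations `DeltaA(lambda) = -ln(1 + dR/100)` for
#' `(dHbO, dHbR)` by least squares over wavelengths: exact with two
#' wavelengths, overdetermined with three (oxygen-challenge configuration).
#' The cerebral oxygenation index `dHbO - dHbR` is returned alongside.
#'
#' @param dr Tibble with `time` and one percent reflectance-change column per
#'   wavelength (named by wavelength in nm), e.g. from [delta_r()] or
#'   [beer_lambert_forward()].
#' @param table Extinction/pathlength table.
#' @return Tibble with columns `time`, `dHbO`, `dHbR` (uM) and
#'   `index = dHbO - dHbR`.
#' @export
beer_lambert_invert <- function(dr, table = pathlength_table()) {
  wls <- setdiff(names(dr), "time")
  if (length(wls) < 2L) stop("need at least two wavelengths", call. = FALSE)
  m <- bl_coef_matrix(table, wls)
  kap <- kappa(m, exact = TRUE)
  if (!is.finite(kap) || kap >= 1e3) {
    stop(
      sprintf(
        "extinction matrix for wavelengths %s is ill-conditioned (condition number %.3g)",
        paste(wls, collapse = "/"), kap
      ),
      call. = FALSE
    )
  }
  da <- -log(1 + as.matrix(dr[wls]) / 100) # samples x wavelengths
  qrm <- qr(m)
  hb <- t(qr.coef(qrm, t(da)))
  tibble::tibble(
    time = dr$time,
    dHbO = hb[, 1], dHbR = hb[, 2],
    index = hb[, 1] - hb[, 2]
  )
}

#' Event-triggered average of a channel
#'
#' Aligns the signal to event onsets and returns the across-event mean with
#' dispersion. Events whose window extends beyond the record are excluded
#' and counted in the `excluded` attribute.
#'
#' @param ts Time-series tibble.
#' @param events Event tibble with an `onset` column.
#' @param window Two-element `(pre, post)` window around onset, s (pre given
#'   as a positive number).
#' @return Tibble with `time` (relative to onset), `mean`, `sd`, `sem`, `n`;
#'   attribute `excluded` counts dropped events.
#' @export
triggered_average <- function(ts, events, window = c(3, 10)) {
  tm <- ts_time(ts)
  v <- ts_values(ts)
  rate <- ts_rate(ts)
  i_pre <- round(window[1] * rate)
  i_post <- round(window[2] * rate)
  rel <- (-i_pre:i_post) / rate
  mat <- list()
  excluded <- 0L
  for (e in seq_len(nrow(events))) {
    i0 <- round((events$onset[e] - tm[1]) * rate) + 1L
    idx <- (i0 - i_pre):(i0 + i_post)
    if (idx[1] < 1L || idx[length(idx)] > length(v)) {
      excluded <- excluded + 1L
      next
    }
    mat[[length(mat) + 1L]] <- v[idx]
  }
  if (length(mat) == 0L) {
    out <- tibble::tibble(
      time = numeric(), mean = numeric(), sd = numeric(),
      sem = numeric(), n = integer()
    )
    attr(out, "excluded") <- excluded
    return(out)
  }
  m <- do.call(rbind, mat)
  n <- nrow(m)
  sds <- if (n > 1L) apply(m, 2, stats::sd) else rep(NA_real_, ncol(m))
  if (n == 1L) warning("single usable event: dispersion undefined")
  out <- tibble::tibble(
    time = rel,
    mean = colMeans(m),
    sd = sds,
    sem = sds / sqrt(n),
    n = n
  )
  attr(out, "excluded") <- excluded
  out
}
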