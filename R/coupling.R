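#' Normalized cross-correlation between two channels
#'
#' Both inputs are zero-phase low-pass filtered (default 1 Hz), mean-removed,
#' and cross-correlated over lags up to `max_lag`. The correlation at lag
#' `l` is `cor(x(t), y(t + l))`, so if `y` is a delayed copy of `x` the peak
#' sits at a positive lag equal to the delay. Normalization by the full-series
#' energies guarantees `|r| <= 1`.
#'
#' @param x,y Time-series tibbles at equal rates.
#' @param max_lag Maximum lag magnitude, s.
#' @param lp Low-pass cutoff applied to both inputs (Hz); `NULL` disables.
#' @return An `ox_xcorr` tibble with columns `lag` and `r`, and a `peak`
#'   attribute `(r_peak, lag_peak)`.
#' @export
xcorr <- function(x, y, max_lag = 5, lp = 1) {
  rx <- ts_rate(x)
  if (abs(rx - ts_rate(y)) > 1e-9 * rx) stop("x and y must share a sampling rate", call. = FALSE)
  xv <- prep_xcorr_input(x, rx, lp)
  yv <- prep_xcorr_input(y, rx, lp)
  n <- min(length(xv), length(yv))
  xv <- xv[1:n]
  yv <- yv[1:n]
  lags <- seq(-round(max_lag * rx), round(max_lag * rx))
  denom <- sqrt(sum(xv^2) * sum(yv^2))
  r <- vapply(lags, function(l) {
    if (l >= 0) sum(xv[1:(n - l)] * yv[(1 + l):n]) else sum(xv[(1 - l):n] * yv[1:(n + l)])
  }, numeric(1)) / denom
  out <- tibble::tibble(lag = lags / rx, r = r)
  ipk <- which.max(abs(r))
  attr(out, "peak") <- list(r_peak = r[ipk], lag_peak = out$lag[ipk])
  class(out) <- c("ox_xcorr", class(out))
  out
}

prep_xcorr_input <- function(ts, rate, lp) {
  v <- ts_values(ts)
  if (stats::sd(v) == 0) stop("zero-variance input to cross-correlation", call. = FALSE)
  if (!is.null(lp)) v <- butter_zp(v, rate, lp, 5, "low")
  v - mean(v)
}

#' Surrogate confidence band for a cross-correlation
#'
#' Builds the null distribution of the cross-correlation by circularly
#' time-shifting `y` by random offsets (which preserves each channel's
#' autocorrelation while destroying their alignment) and takes per-lag
#' 2.5/97.5 percentiles over `n` surrogates.
#'
#' @inheritParams xcorr
#' @param n Number of surrogate shifts (>= 100).
#' @param seed Integer seed for the surrogate draws.
#' @return An `ox_xcorr` tibble with columns `lag`, `r`, `ci_lo`, `ci_hi`.
#' @export
surrogate_ci <- function(x, y, max_lag = 5, n = 1000, seed = 1, lp = 1) {
  if (n < 100) stop("use at least 100 surrogates", call. = FALSE)
  rx <- ts_rate(x)
  xv <- prep_xcorr_input(x, rx, lp)
  yv <- prep_xcorr_input(y, rx, lp)
  m <- min(length(xv), length(yv))
  xv <- xv[1:m]
  yv <- yv[1:m]
  nl <- round(max_lag * rx)
  lags <- seq(-nl, nl)
  # circular cross-correlation once via FFT; a circular shift of y by s
  # turns c(l) into c(l + s), so each surrogate is a lookup
  cc <- Re(stats::fft(Conj(stats::fft(xv)) * stats::fft(yv), inverse = TRUE)) / m
  cc <- cc / sqrt(mean(xv^2) * mean(yv^2))
  at <- function(l) cc[(l %% m) + 1L]
  shifts <- with_seed(seed, sample.int(m - 1L, n, replace = TRUE))
  sur <- vapply(shifts, function(s) at(lags + s), numeric(length(lags)))
  band <- apply(sur, 1L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- tibble::tibble(
    lag = lags / rx, r = at(lags),
    ci_lo = band[1L, ], ci_hi = band[2L, ]
  )
  ipk <- which.max(abs(out$r))
  attr(out, "peak") <- list(r_peak = out$r[ipk], lag_peak = out$lag[ipk])
  class(out) <- c("ox_xcorr", class(out))
  out
}

#' @export
autoplot.ox_xcorr <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$r))
  if (all(c("ci_lo", "ci_hi") %in% names(object))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      fill = "steelblue", alpha = 0.3
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "lag (s)", y = "correlation") +
    ggplot2::theme_minimal()
}

# Averaged multitaper auto/cross spectra over non-overlapping segments.
mt_spectra <- function(channels, rate, nseg, nw, k_tapers) {
  n <- min(lengths(channels))
  seg_len <- n %/% nseg
  if (seg_len < 8L) stop("record too short for the requested segmentation", call. = FALSE)
  tap <- dpss_tapers(seg_len, nw, k_tapers)
  nf <- seg_len %/% 2L + 1L
  ests <- lapply(channels, function(v) {
    v <- v[1:(seg_len * nseg)] - mean(v)
    segs <- matrix(v, seg_len, nseg)
    out <- array(0 + 0i, dim = c(nf, nseg * k_tapers))
    idx <- 1L
    for (s in seq_len(nseg)) {
      tx <- segs[, s] * tap # seg_len x k
      fx <- stats::mvfft(tx)[1:nf, , drop = FALSE]
      out[, idx:(idx + k_tapers - 1L)] <- fx
      idx <- idx + k_tapers
    }
    out
  })
  freqs <- (0:(nf - 1L)) * rate / seg_len
  cross <- function(a, b) rowMeans(ests[[a]] * Conj(ests[[b]]))
  list(freqs = freqs, cross = cross, n_est = nseg * k_tapers)
}

#' Squared coherence between two channels
#'
#' Magnitude-squared coherence `C2 = |Sxy|^2 / (Sx Sy)` from multitaper
#' spectra averaged over non-overlapping segments. With a single averaged
#' estimate the coherence is identically 1, so at least two (and by default
#' ten) segments are required.
#'
#' @param x,y Time-series tibbles at equal rates.
#' @param nseg Number of non-overlapping segments (>= 2).
#' @param nw Time-bandwidth product of the per-segment tapers.
#' @param k_tapers Tapers per segment.
#' @return An `ox_coherence` tibble with columns `freq` and `c2` and an
#'   `n_est` attribute (number of averaged spectral estimates).
#' @export
coherence <- function(x, y, nseg = 10, nw = 3, k_tapers = 5) {
  if (nseg < 2) stop("coherence from a single window is identically 1; provide more data", call. = FALSE)
  rate <- ts_rate(x)
  if (abs(rate - ts_rate(y)) > 1e-9 * rate) stop("x and y must share a sampling rate", call. = FALSE)
  sp <- mt_spectra(list(x = ts_values(x), y = ts_values(y)), rate, nseg, nw, k_tapers)
  sxx <- Re(sp$cross("x", "x"))
  syy <- Re(sp$cross("y", "y"))
  sxy <- sp$cross("x", "y")
  c2 <- Mod(sxy)^2 / (sxx * syy)
  out <- tibble::tibble(freq = sp$freqs, c2 = pmin(pmax(c2, 0), 1))
  attr(out, "n_est") <- sp$n_est
  class(out) <- c("ox_coherence", class(out))
  out
}

#' Squared partial coherence given a conditioning channel
#'
#' Coherence between `x` and `y` after removing from each the component
#' linearly predictable from `z`:
#' `PC2 = |Sxy Szz - Sxz Szy|^2 / ((Sxx Szz - |Sxz|^2)(Syy Szz - |Syz|^2))`.
#' Frequencies where a denominator spectrum falls below `1e-12` of its
#' maximum are masked with `NA`.
#'
#' @inheritParams coherence
#' @param z Conditioning time-series tibble.
#' @return An `ox_coherence` tibble with columns `freq`, `c2` (ordinary) and
#'   `pc2` (partial).
#' @export
partial_coherence <- function(x, y, z, nseg = 10, nw = 3, k_tapers = 5) {
  rate <- ts_rate(x)
  if (abs(rate - ts_rate(y)) > 1e-9 * rate || abs(rate - ts_rate(z)) > 1e-9 * rate) {
    stop("all channels must share a sampling rate", call. = FALSE)
  }
  sp <- mt_spectra(
    list(x = ts_values(x), y = ts_values(y), z = ts_values(z)),
    rate, nseg, nw, k_tapers
  )
  sxx <- Re(sp$cross("x", "x"))
  syy <- Re(sp$cross("y", "y"))
  szz <- Re(sp$cross("z", "z"))
  sxy <- sp$cross("x", "y")
  sxz <- sp$cross("x", "z")
  syz <- sp$cross("y", "z")
  num <- Mod(sxy * szz - sxz * Conj(syz))^2
  d1 <- sxx * szz - Mod(sxz)^2
  d2 <- syy * szz - Mod(syz)^2
  pc2 <- num / (d1 * d2)
  mask <- d1 <= 1e-12 * max(sxx * szz) | d2 <= 1e-12 * max(syy * szz) |
    szz <= 1e-12 * max(szz) | !is.finite(pc2)
  # total removal (e.g. x = z): numerator vanishes at higher order than the
  # denominator, so the residual coherence is 0, not undefined
  num_rel <- num / pmax(sxx * syy * szz^2, .Machine$double.xmin)
  pc2[mask] <- ifelse(num_rel[mask] < 1e-8, 0, NA_real_)
  out <- tibble::tibble(
    freq = sp$freqs,
    c2 = pmin(pmax(Mod(sxy)^2 / (sxx * syy), 0), 1),
    pc2 = pmin(pc2, 1)
  )
  attr(out, "n_est") <- sp$n_est
  class(out) <- c("ox_coherence", class(out))
  out
}

#' @export
autoplot.ox_coherence <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    -"freq",
    names_to = "measure", values_to = "coherence"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$freq, y = .data$coherence,
    colour = .data$measure
  )) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "frequency (Hz)", y = "squared coherence") +
    ggplot2::theme_minimal()
}

#' Band-resolved cross-correlogram between LFP power and an oxygen signal
#'
#' Splits the LFP into narrow frequency bands via the multitaper spectrogram,
#' then cross-correlates the power time course of every band with the
#' (1 Hz low-passed) oxygen trace, resampled to the spectrogram's time grid.
#'
#' @param lfp LFP time-series tibble.
#' @param o2 Oxygen time-series tibble.
#' @param band_lo,band_hi,band_step Band grid in Hz.
#' @param max_lag Maximum lag, s.
#' @param window,step Spectrogram window and hop, s.
#' @param lp Low-pass cutoff applied to the oxygen trace and band powers, Hz.
#' @return Long tibble with columns `freq`, `lag`, `r` (class
#'   `ox_bandxcorr`).
#' @export
band_crosscorrelogram <- function(lfp, o2, band_lo = 0.5, band_hi = 150,
                                  band_step = 1, max_lag = 5,
                                  window = 1, step = 0.1, lp = 1) {
  spec <- multitaper_spectrogram(lfp, window = window, step = step)
  spec_rate <- 1 / step
  o2v <- ts_values(o2)
  o2r <- ts_rate(o2)
  if (stats::sd(o2v) == 0) stop("oxygen trace is constant", call. = FALSE)
  o2f <- butter_zp(o2v, o2r, min(lp, 0.45 * spec_rate), 5, "low")
  o2i <- stats::approx(ts_time(o2), o2f, spec$times, rule = 2)$y
  edges <- seq(band_lo, band_hi, by = band_step)
  res <- purrr::map_dfr(utils::head(seq_along(edges), -1L), function(b) {
    cols <- spec$freqs >= edges[b] & spec$freqs < edges[b + 1L]
    if (!any(cols)) {
      return(NULL)
    }
    p <- rowSums(spec$power[, cols, drop = FALSE])
    xc <- xcorr(
      tibble::tibble(time = spec$times, value = p),
      tibble::tibble(time = spec$times, value = o2i),
      max_lag = max_lag, lp = min(lp, 0.45 * spec_rate)
    )
    tibble::tibble(freq = (edges[b] + edges[b + 1L]) / 2, lag = xc$lag, r = xc$r)
  })
  class(res) <- c("ox_bandxcorr", class(res))
  res
}

#' @export
autoplot.ox_bandxcorr <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$freq, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "lag (s)", y = "LFP band (Hz)", fill = "r") +
    ggplot2::theme_minimal()
}

#' Exact Wilcoxon signed-rank test
#'
#' Exact p-value of the signed-rank statistic by full enumeration of the
#' 2^n equiprobable sign assignments (implemented as a dynamic-programming
#' convolution over the rank values, which enumerates the same distribution).
#' Zero differences are dropped; ties receive average ranks. The two-sided
#' p-value doubles the smaller tail (capped at 1).
#'
#' @param diffs Numeric vector of paired differences (1 <= n <= 25 after
#'   dropping zeros).
#' @param sides `"two"` (default) or `"one"` (upper tail, positive shift).
#' @return The exact p-value.
#' @export
#' @examples
#' wilcoxon_exact(c(0.8, 1.2, 0.5, 2.1, 0.9, 1.7)) # six positive pairs
wilcoxon_exact <- function(diffs, sides = c("two", "one")) {
  sides <- match.arg(sides)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero: test undefined", call. = FALSE)
  if (n > 25L) stop("exact enumeration supported for n <= 25", call. = FALSE)
  rk <- rank(abs(d)) # average ranks for ties
  ir <- as.integer(round(2 * rk)) # integer grid (half-ranks doubled)
  w_obs <- sum(ir[d > 0])
  total <- sum(ir)
  # distribution of W2 = 2*W over all sign assignments
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (r in ir) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  counts <- counts / 2^n
  p_ge <- sum(counts[(w_obs + 1L):(total + 1L)])
  p_le <- sum(counts[1L:(w_obs + 1L)])
  if (sides == "one") p_ge else min(1, 2 * min(p_ge, p_le))
}
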