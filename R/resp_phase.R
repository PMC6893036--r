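# Respiration signal processing, phosphorescence-lifetime oximetry, and
# respiration-phase-resolved arterial oxygen analysis.

#' Stern-Volmer calibration for phosphorescence-lifetime oximetry
#'
#' `1/tau = 1/tau0 + kq * pO2`: oxygen quenches the probe's phosphorescence,
#' shortening its lifetime. The constants are probe-specific and must come
#' from an independent calibration; the defaults are representative of
#' two-photon phosphorescent oxygen probes.
#'
#' @param tau0 Zero-oxygen lifetime, microseconds.
#' @param kq Quenching constant, 1/(us mmHg).
#' @return Object of class `oximetry_cal`.
#' @export
oximetry_calibration <- function(tau0 = 40, kq = 2.8e-4) {
  if (tau0 <= 0 || kq <= 0) stop("calibration constants must be positive", call. = FALSE)
  structure(list(tau0 = tau0, kq = kq), class = "oximetry_cal")
}

#' Map phosphorescence lifetime to oxygen tension (and back)
#'
#' @param tau Lifetime(s), us.
#' @param calib An [oximetry_calibration()].
#' @return Oxygen tension, mmHg.
#' @export
stern_volmer_po2 <- function(tau, calib) {
  (1 / tau - 1 / calib$tau0) / calib$kq
}

#' @rdname stern_volmer_po2
#' @param po2 Oxygen tension(s), mmHg.
#' @export
stern_volmer_tau <- function(po2, calib) {
  1 / (1 / calib$tau0 + calib$kq * po2)
}

#' Phosphorescence decay set
#'
#' Container for a sequence of photon-count decay records acquired at a
#' common digitization rate: timestamps, a decays x samples count matrix and
#' the initial gate-discard window.
#'
#' @param timestamps Decay acquisition times, s.
#' @param counts Matrix of photon signal, one row per decay.
#' @param rate Digitization rate, Hz.
#' @param discard_us Initial portion of every decay discarded before
#'   fitting, us.
#' @return Object of class `ox_decays`.
#' @export
decay_set <- function(timestamps, counts, rate = 1.25e6, discard_us = 5.6) {
  stopifnot(length(timestamps) == nrow(counts))
  if (ncol(counts) <= ceiling(discard_us * 1e-6 * rate)) {
    stop("decay records shorter than the discard window", call. = FALSE)
  }
  structure(
    list(
      timestamps = as.numeric(timestamps), counts = counts,
      rate = rate, discard_us = discard_us
    ),
    class = "ox_decays"
  )
}

#' @export
print.ox_decays <- function(x, ...) {
  cat(sprintf(
    "<ox_decays> %d decays x %d samples @ %.4g MHz (discard %.2g us)\n",
    nrow(x$counts), ncol(x$counts), x$rate / 1e6, x$discard_us
  ))
  invisible(x)
}

#' Detect expiratory peaks in a thermocouple respiration trace
#'
#' Expiratory peaks (upward deflections of the nasal thermocouple) are
#' located at negative-going zero crossings of the first derivative of the
#' (<= 30 Hz low-passed) signal. The instantaneous respiratory rate is the
#' reciprocal inter-peak interval, emitted as a step series.
#'
#' @param thermo Time-series tibble, already band-limited below 30 Hz.
#' @param min_interval Minimum inter-peak interval, s (respiration above
#'   1/min_interval Hz is not physiological for head-fixed mice).
#' @param out_rate Sampling rate of the instantaneous-rate series, Hz.
#' @return Object of class `ox_resp`: `peaks` (times, s), `rate`
#'   (time-series tibble, Hz), and the input trace.
#' @export
detect_expiratory_peaks <- function(thermo, min_interval = 0.15, out_rate = 30) {
  v <- ts_values(thermo)
  tm <- ts_time(thermo)
  dv <- diff(v)
  cross <- which(dv[-length(dv)] > 0 & dv[-1L] <= 0) + 1L
  # amplitude gate: derivative zero crossings in the flat inter-breath
  # baseline are not expiratory peaks
  if (length(cross) >= 2L) {
    q <- stats::quantile(v, c(0.05, 0.95), names = FALSE)
    if (q[2] > q[1]) cross <- cross[v[cross] >= q[1] + 0.3 * (q[2] - q[1])]
  }
  if (length(cross) >= 2L) {
    keep <- logical(length(cross))
    last <- -Inf
    for (i in seq_along(cross)) {
      if (tm[cross[i]] - last >= min_interval) {
        keep[i] <- TRUE
        last <- tm[cross[i]]
      } else if (v[cross[i]] > v[cross[max(which(keep))]]) {
        keep[max(which(keep))] <- FALSE
        keep[i] <- TRUE
        last <- tm[cross[i]]
      }
    }
    cross <- cross[keep]
  }
  if (length(cross) < 3L) stop("fewer than 3 expiratory peaks detected", call. = FALSE)
  peaks <- tm[cross]
  iv <- diff(peaks)
  grid <- seq(peaks[1], peaks[length(peaks)], by = 1 / out_rate)
  rate_v <- 1 / iv[pmin(findInterval(grid, peaks), length(iv))]
  rate_ts <- tibble::tibble(time = grid, value = rate_v)
  attr(rate_ts, "units") <- "Hz"
  structure(
    list(peaks = peaks, rate = rate_ts, thermo = thermo),
    class = "ox_resp"
  )
}

#' @export
print.ox_resp <- function(x, ...) {
  cat(sprintf(
    "<ox_resp> %d expiratory peaks | mean rate %.3g Hz\n",
    length(x$peaks), mean(x$rate$value)
  ))
  invisible(x)
}

#' Regular-respiration epoch selection
#'
#' Scores sliding epochs of the instantaneous respiratory-rate series against
#' the regularity criteria used for phase-resolved oximetry: epoch SD at most
#' `sd_max`, mean-to-SD ratio above `ratio_min`, rate never above `max_rate`,
#' and mean within `mean_tol` of the target regime.
#'
#' @param rate Time-series tibble of instantaneous respiratory rate (Hz).
#' @param mean_target Target mean rate of the regular regime, Hz.
#' @param sd_max Maximum epoch SD, Hz.
#' @param ratio_min Minimum mean/SD ratio.
#' @param max_rate Physiological ceiling, Hz.
#' @param mean_tol Allowed deviation of the epoch mean from `mean_target`, Hz.
#' @param epoch,step Epoch length and hop, s.
#' @return Tibble of epochs with `onset`, `offset`, `mean`, `sd`, `ratio`,
#'   `accepted`.
#' @export
regularity_filter <- function(rate, mean_target = 2.5, sd_max = 0.6,
                              ratio_min = 4, max_rate = 5, mean_tol = 1,
                              epoch = 10, step = epoch / 2) {
  tm <- ts_time(rate)
  v <- ts_values(rate)
  if (length(v) == 0L) stop("empty rate series", call. = FALSE)
  starts <- seq(tm[1], max(tm[1], tm[length(tm)] - epoch), by = step)
  purrr::map_dfr(starts, function(s) {
    sel <- tm >= s & tm < s + epoch
    if (sum(sel) < 2L) {
      return(NULL)
    }
    m <- mean(v[sel])
    sdv <- stats::sd(v[sel])
    ratio <- if (sdv == 0) Inf else m / sdv
    tibble::tibble(
      onset = s, offset = s + epoch, mean = m, sd = sdv, ratio = ratio,
      accepted = sdv <= sd_max & ratio > ratio_min &
        max(v[sel]) <= max_rate & abs(m - mean_target) <= mean_tol
    )
  })
}

# Weighted log-linear single-exponential fit with a fixed background:
# fast, used to seed the full fit and (vectorized) for per-decay estimates.
loglin_lifetime <- function(ys, tt) {
  pos <- ys > 0
  if (sum(pos) < 5L) {
    return(c(NA_real_, NA_real_))
  }
  w <- ys[pos] # ~inverse-variance weights for log counts
  lx <- tt[pos]
  ly <- log(ys[pos])
  wm_x <- sum(w * lx) / sum(w)
  wm_y <- sum(w * ly) / sum(w)
  slope <- sum(w * (lx - wm_x) * (ly - wm_y)) / sum(w * (lx - wm_x)^2)
  if (!is.finite(slope) || slope >= 0) {
    return(c(NA_real_, NA_real_))
  }
  tau <- -1 / slope
  c(tau, exp(wm_y + wm_x / tau))
}

# Fit a single-exponential lifetime (us) to a mean decay record by full
# three-parameter nonlinear least squares (amplitude, lifetime,
# background), seeded by a weighted log-linear fit with tail background.
fit_lifetime <- function(y, rate, discard_us) {
  n <- length(y)
  i0 <- ceiling(discard_us * 1e-6 * rate) + 1L
  tail_idx <- (n - max(3L, round(0.08 * n)) + 1L):n
  tt <- (seq_len(n) - i0)[i0:n] / rate * 1e6 # us from fit start
  yy <- y[i0:n]
  bg0 <- mean(y[tail_idx])
  st <- loglin_lifetime(yy - bg0, tt)
  if (!is.finite(st[1])) {
    return(NA_real_)
  }
  df <- data.frame(t = tt, y = yy)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-t / tau) + bg,
      data = df,
      start = list(A = st[2], tau = st[1], bg = bg0),
      lower = c(0, 1e-3, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(st[1])
  }
  tau <- stats::coef(fit)[["tau"]]
  if (!is.finite(tau) || tau <= 0) NA_real_ else tau
}

# Per-group lifetime fits on a decay set. Groups of averaged decays use the
# scalar fit; group = 1 (per-decay, used by the permutation test) runs a
# fully vectorized matrix version of the same weighted log-linear fit with
# tail-background refinement.
decay_lifetimes <- function(decays, group = 1L) {
  cm <- decays$counts
  nd <- nrow(cm)
  ng <- nd %/% group
  if (group > 1L) {
    return(vapply(seq_len(ng), function(g) {
      rows <- ((g - 1L) * group + 1L):(g * group)
      fit_lifetime(colMeans(cm[rows, , drop = FALSE]), decays$rate, decays$discard_us)
    }, numeric(1)))
  }
  n <- ncol(cm)
  i0 <- ceiling(decays$discard_us * 1e-6 * decays$rate) + 1L
  tail_idx <- (n - max(3L, round(0.08 * n)) + 1L):n
  tt_full <- (seq_len(n) - i0) / decays$rate * 1e6
  tt <- tt_full[i0:n]
  yy <- cm[, i0:n, drop = FALSE]
  bg <- rowMeans(cm[, tail_idx, drop = FALSE])
  tau <- rep(NA_real_, nd)
  # single pass: per-decay estimates only feed the permutation test, where
  # the (common-mode) tail-background bias cancels
  ys <- yy - bg
  w <- pmax(ys, 0)
  ly <- log(pmax(ys, 1e-12))
  sw <- rowSums(w)
  wx <- (w %*% tt)[, 1] / sw
  wy <- rowSums(w * ly) / sw
  wl <- w * (ly - wy)
  sxy <- (wl %*% tt)[, 1] - wx * rowSums(wl)
  sxx <- (w %*% tt^2)[, 1] - 2 * wx * (w %*% tt)[, 1] + wx^2 * sw
  slope <- sxy / sxx
  ok <- is.finite(slope) & slope < 0 & rowSums(ys > 0) >= 5L
  tau[ok] <- -1 / slope[ok]
  tau
}

#' Oxygen tension from grouped phosphorescence decays
#'
#' Averages consecutive groups of decays, fits a single-exponential lifetime
#' to each group mean (after the gate discard, with tail-estimated
#' background), and converts lifetimes to oxygen tension through the
#' Stern-Volmer relation. Groups with non-positive fitted lifetimes are
#' rejected with a warning.
#'
#' @param decays An [decay_set()] object.
#' @param group Decays averaged per lifetime estimate.
#' @param calib An [oximetry_calibration()].
#' @return Time-series tibble (time = group centers, value = mmHg).
#' @export
lifetime_to_po2 <- function(decays, group = 3000, calib = oximetry_calibration()) {
  stopifnot(inherits(decays, "ox_decays"))
  nd <- nrow(decays$counts)
  if (nd < group) stop("fewer decays than one group", call. = FALSE)
  taus <- decay_lifetimes(decays, group = group)
  ng <- length(taus)
  centers <- vapply(seq_len(ng), function(g) {
    mean(decays$timestamps[((g - 1L) * group + 1L):(g * group)])
  }, numeric(1))
  bad <- !is.finite(taus)
  if (any(bad)) warning(sprintf("%d group(s) rejected: non-positive fitted lifetime", sum(bad)))
  out <- tibble::tibble(
    time = centers[!bad],
    value = stern_volmer_po2(taus[!bad], calib)
  )
  attr(out, "units") <- "mmHg"
  out
}

#' Respiration-phase-aligned arterial oxygen profile
#'
#' Assigns every decay the elapsed time since the most recent expiratory
#' peak, pools decays across cycles into fixed-width phase bins, and fits a
#' lifetime (hence PaO2) per pooled bin. Cycles longer than mean + 3 SD are
#' excluded as irregular. The smoothed column applies the circular binomial
#' filter used for display and extremum localization.
#'
#' @param decays An [decay_set()] object.
#' @param resp An [detect_expiratory_peaks()] result (or a numeric vector of
#'   peak times).
#' @param bin Phase bin width, s.
#' @param calib An [oximetry_calibration()].
#' @param cycle_sd_max Cycles longer than mean + `cycle_sd_max` SD are
#'   dropped.
#' @return An `ox_cycleprofile` tibble with `bin_time` (bin centers, s since
#'   expiratory peak), `pao2`, `count`, `smoothed`; attributes: `bin`,
#'   `cycle` (median cycle length, s), `decay_po2` (per-decay tibble used by
#'   [respiration_locked_test()]).
#' @export
phase_align <- function(decays, resp, bin = 0.02,
                        calib = oximetry_calibration(), cycle_sd_max = 3) {
  stopifnot(inherits(decays, "ox_decays"))
  peaks <- if (inherits(resp, "ox_resp")) resp$peaks else as.numeric(resp)
  if (length(peaks) < 3L) stop("need at least 3 expiratory peaks", call. = FALSE)
  cyc <- diff(peaks)
  ok_cycle <- cyc <= mean(cyc) + cycle_sd_max * stats::sd(cyc) + 1e-9
  ts_d <- decays$timestamps
  idx <- findInterval(ts_d, peaks)
  in_cycle <- idx >= 1L & idx <= length(cyc)
  in_cycle[in_cycle] <- ok_cycle[idx[in_cycle]]
  phase <- ts_d - peaks[pmax(idx, 1L)]
  n_bins <- max(3L, floor(stats::median(cyc) / bin + 1e-9))
  use <- in_cycle & phase < n_bins * bin
  bin_id <- floor(phase / bin) + 1L
  pao2 <- rep(NA_real_, n_bins)
  counts <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    rows <- which(use & bin_id == b)
    counts[b] <- length(rows)
    if (counts[b] == 0L) next
    y <- colMeans(decays$counts[rows, , drop = FALSE])
    tau <- fit_lifetime(y, decays$rate, decays$discard_us)
    if (is.finite(tau)) pao2[b] <- stern_volmer_po2(tau, calib)
  }
  out <- tibble::tibble(
    bin_time = (seq_len(n_bins) - 0.5) * bin,
    pao2 = pao2,
    count = counts
  )
  out$smoothed <- binomial_smooth(out$pao2)
  # per-decay PaO2 estimates for the permutation test
  tau_d <- decay_lifetimes(decays, group = 1L)
  po2_d <- stern_volmer_po2(tau_d, calib)
  keep <- use & is.finite(po2_d)
  attr(out, "decay_po2") <- tibble::tibble(
    bin = bin_id[keep], po2 = po2_d[keep]
  )
  attr(out, "bin") <- bin
  attr(out, "cycle") <- stats::median(cyc)
  class(out) <- c("ox_cycleprofile", class(out))
  out
}

#' Circular binomial smoothing of a cycle profile
#'
#' Repeated circular convolution with the first-order binomial kernel
#' `[1, 2, 1]/4` (five repetitions by default). DC gain is exactly 1; a
#' sinusoid over `n` circular bins is attenuated by `cos(pi/n)^(2 reps)`
#' with unchanged phase.
#'
#' @param profile Numeric vector (circular), possibly with `NA` bins.
#' @param reps Number of repetitions.
#' @return Smoothed numeric vector.
#' @export
binomial_smooth <- function(profile, reps = 5) {
  x <- profile
  n <- length(x)
  if (n < 3L) stop("need at least 3 bins", call. = FALSE)
  na <- !is.finite(x)
  if (any(na) && !all(na)) x[na] <- mean(x[!na]) # mask filled for smoothing
  for (i in seq_len(reps)) {
    x <- (c(x[n], x[-n]) + 2 * x + c(x[-1L], x[1L])) / 4
  }
  x[na] <- NA_real_
  x
}

#' Extremal phase windows of a cycle profile
#'
#' Locates the smoothed profile's minimum and maximum and averages the raw
#' per-bin PaO2 over a `window`-wide (default 40 ms, two-bin) span at each
#' extremum, giving the per-recording `PaO2(Tmin)` / `PaO2(Tmax)` pair used
#' for paired testing across recordings.
#'
#' @param profile An `ox_cycleprofile` from [phase_align()].
#' @param window Averaging window, s.
#' @return One-row tibble: `tmin`, `tmax` (window centers, s), `pao2_min`,
#'   `pao2_max`.
#' @export
tmin_tmax <- function(profile, window = 0.04) {
  stopifnot(inherits(profile, "ox_cycleprofile"))
  s <- profile$smoothed
  if (all(!is.finite(s)) || diff(range(s, na.rm = TRUE)) < 1e-12) {
    warning("flat profile: extremal windows undefined")
    return(tibble::tibble(
      tmin = NA_real_, tmax = NA_real_,
      pao2_min = NA_real_, pao2_max = NA_real_
    ))
  }
  bin <- attr(profile, "bin")
  n <- nrow(profile)
  half <- max(1L, round(window / bin / 2))
  win_mean <- function(i) {
    idx <- ((i - half):(i + half - 1L) - 1L) %% n + 1L # window of 2*half bins
    mean(profile$pao2[idx], na.rm = TRUE)
  }
  imin <- which.min(s)
  imax <- which.max(s)
  tibble::tibble(
    tmin = profile$bin_time[imin], tmax = profile$bin_time[imax],
    pao2_min = win_mean(imin), pao2_max = win_mean(imax)
  )
}

#' Permutation test for respiration-locked arterial oxygen fluctuations
#'
#' Computes the power spectrum of the phase-binned PaO2 profile and tests
#' the power at the respiratory frequency against a null built by randomly
#' permuting the decay-to-phase assignment (which destroys phase locking
#' while preserving the marginal PaO2 distribution). Significance is
#' declared when the observed power exceeds the 95th percentile of the
#' surrogate powers at that frequency.
#'
#' @param profile An `ox_cycleprofile` from [phase_align()] (its
#'   `decay_po2` attribute provides the per-decay sequence), or a tibble
#'   with columns `bin` and `po2`.
#' @param resp_freq Respiratory frequency to test, Hz; defaults to the
#'   profile's fundamental (one cycle per profile).
#' @param n_surrogates Number of permutations (>= 1000).
#' @param seed RNG seed for the permutations.
#' @return Object of class `ox_locktest`: `peak_freq` (argmax of the
#'   observed spectrum), `power` at the respiratory frequency, `spectrum`
#'   tibble (`freq`, `power`, `ci95`), `significant`, permutation `p`.
#' @export
respiration_locked_test <- function(profile, resp_freq = NULL,
                                    n_surrogates = 10000, seed = 1) {
  if (n_surrogates < 1000) stop("use at least 1000 surrogates", call. = FALSE)
  if (inherits(profile, "ox_cycleprofile")) {
    dp <- attr(profile, "decay_po2")
    n_bins <- nrow(profile)
    bin_w <- attr(profile, "bin")
  } else {
    dp <- profile
    n_bins <- max(dp$bin)
    bin_w <- attr(profile, "bin") %||% 0.02
  }
  cycle <- n_bins * bin_w
  freqs <- (1:(n_bins %/% 2)) / cycle
  if (is.null(resp_freq)) resp_freq <- 1 / cycle
  k <- which.min(abs(freqs - resp_freq))
  if (abs(freqs[k] - resp_freq) > 0.5 / cycle) {
    stop("respiratory frequency outside the spectral range of the profile", call. = FALSE)
  }
  # order decays by bin once: permuting the decay-to-bin assignment is then
  # equivalent to permuting the PaO2 values and cutting at fixed boundaries
  ord <- order(dp$bin)
  v <- dp$po2[ord]
  sizes <- tabulate(dp$bin, nbins = n_bins)
  ends <- cumsum(sizes)
  nonempty <- sizes > 0L
  prof_of <- function(vals) {
    cs <- c(0, cumsum(vals))
    prof <- rep(NA_real_, n_bins)
    prof[nonempty] <- diff(cs[c(1L, ends + 1L)])[nonempty] / sizes[nonempty]
    prof[!is.finite(prof)] <- mean(prof[is.finite(prof)])
    prof
  }
  spec_fast <- function(vals) {
    prof <- prof_of(vals)
    p <- Mod(stats::fft(prof - mean(prof)))^2 / n_bins
    p[2:(n_bins %/% 2 + 1L)]
  }
  obs <- spec_fast(v)
  nv <- length(v)
  sur <- with_seed(seed, {
    vapply(seq_len(n_surrogates), function(i) {
      spec_fast(v[sample.int(nv)])
    }, numeric(length(obs)))
  })
  ci95 <- apply(sur, 1L, stats::quantile, probs = 0.95, names = FALSE)
  p_perm <- (1 + sum(sur[k, ] >= obs[k])) / (1 + n_surrogates)
  structure(
    list(
      peak_freq = freqs[which.max(obs)],
      resp_freq = freqs[k],
      power = obs[k],
      spectrum = tibble::tibble(freq = freqs, power = obs, ci95 = ci95),
      significant = obs[k] > ci95[k],
      p = p_perm,
      n_surrogates = n_surrogates
    ),
    class = "ox_locktest"
  )
}

#' @export
glance.ox_locktest <- function(x, ...) {
  tibble::tibble(
    peak_freq = x$peak_freq, resp_freq = x$resp_freq,
    power = x$power, significant = x$significant, p = x$p
  )
}

#' @export
print.ox_locktest <- function(x, ...) {
  cat(sprintf(
    "<ox_locktest> power %.4g at %.3g Hz (spectral peak %.3g Hz): %s (perm. p = %.4g)\n",
    x$power, x$resp_freq, x$peak_freq,
    if (x$significant) "significant" else "not significant", x$p
  ))
  invisible(x)
}

#' @export
autoplot.ox_cycleprofile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$pao2, size = .data$count), alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "firebrick") +
    ggplot2::labs(
      x = "time since expiratory peak (s)", y = expression(PaO[2] ~ (mmHg)),
      size = "decays"
    ) +
    ggplot2::theme_minimal()
}
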