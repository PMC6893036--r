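# LFP spectral analysis, MUA spike rates, and fast-/regular-spiking
# waveform classification.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` Slepian tapers of length `n` with time-bandwidth
#' product `nw`, via the classical tridiagonal matrix that commutes with the
#' spectral concentration operator. Tapers are unit-energy columns. Families
#' are cached per `(n, nw, k)`.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (half-bandwidth `nw/n` cycles/sample).
#' @param k Number of tapers (`k <= 2 nw - 1` recommended).
#' @return `n x k` matrix of tapers.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 8, nw > 0, k >= 1)
  cache_get_or(sprintf("dpss_%d_%g_%d", n, nw, k), function() {
    w <- nw / n
    i <- 0:(n - 1)
    dg <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
    od <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
    tm <- matrix(0, n, n)
    tm[cbind(i + 1, i + 1)] <- dg
    tm[cbind(1:(n - 1), 2:n)] <- od
    tm[cbind(2:n, 1:(n - 1))] <- od
    ev <- eigen(tm, symmetric = TRUE)
    tap <- ev$vectors[, seq_len(k), drop = FALSE]
    tap <- sweep(tap, 2, sqrt(colSums(tap^2)), "/")
    # sign convention: make each taper's leading lobe positive
    sg <- sign(colSums(tap * seq_len(n)^0) + 1e-12)
    sg[sg == 0] <- 1
    sweep(tap, 2, sg, "*")
  })
}

#' Sliding-window multitaper spectrogram
#'
#' Slepian multitaper power estimates on a sliding window. The default
#' configuration (1 s window, time-bandwidth 5, nine tapers) targets LFP
#' recordings where gamma-band power is the quantity of interest.
#'
#' @param lfp Time-series tibble.
#' @param window Window length, s.
#' @param step Hop between consecutive windows, s.
#' @param nw Time-bandwidth product.
#' @param n_tapers Number of tapers averaged.
#' @return An object of class `ox_spectrogram`: list with `power`
#'   (time x frequency), `times` (window centers, s), `freqs` (Hz), `window`,
#'   `n_tapers`.
#' @export
multitaper_spectrogram <- function(lfp, window = 1, step = window / 2,
                                   nw = 5, n_tapers = 9) {
  rate <- ts_rate(lfp)
  v <- ts_values(lfp)
  nwin <- round(window * rate)
  if (nwin > length(v)) stop("window longer than the record", call. = FALSE)
  hop <- max(1L, round(step * rate))
  starts <- seq(1L, length(v) - nwin + 1L, by = hop)
  tap <- dpss_tapers(nwin, nw, n_tapers)
  nf <- nwin %/% 2L + 1L
  power <- matrix(0, length(starts), nf)
  for (s in seq_along(starts)) {
    seg <- v[starts[s]:(starts[s] + nwin - 1L)]
    fx <- stats::mvfft(seg * tap)[1:nf, , drop = FALSE]
    power[s, ] <- rowMeans(Mod(fx)^2) / rate
  }
  tm <- ts_time(lfp)
  structure(
    list(
      power = power,
      times = tm[starts] + (nwin - 1) / (2 * rate),
      freqs = (0:(nf - 1L)) * rate / nwin,
      window = window, n_tapers = n_tapers, nw = nw
    ),
    class = "ox_spectrogram"
  )
}

#' @export
tidy.ox_spectrogram <- function(x, ...) {
  tibble::tibble(
    time = rep(x$times, times = length(x$freqs)),
    freq = rep(x$freqs, each = length(x$times)),
    power = as.vector(x$power)
  )
}

#' @export
print.ox_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<ox_spectrogram> %d windows x %d freqs | window %.3g s, %d tapers (NW = %g)\n",
    nrow(x$power), ncol(x$power), x$window, x$n_tapers, x$nw
  ))
  invisible(x)
}

#' @export
autoplot.ox_spectrogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq, fill = log10(.data$power + 1e-20))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Band-integrated spectrogram power
#'
#' @param spec An `ox_spectrogram`.
#' @param band Two-element frequency band in Hz; the default is the gamma
#'   band (40-100 Hz), the LFP band most tightly coupled to vasodilation.
#' @return Time-series tibble of band power at the spectrogram resolution.
#' @export
gamma_power <- function(spec, band = c(40, 100)) {
  stopifnot(inherits(spec, "ox_spectrogram"))
  if (band[1] < min(spec$freqs) || band[2] > max(spec$freqs)) {
    stop("band outside the spectrogram frequency range", call. = FALSE)
  }
  cols <- spec$freqs >= band[1] & spec$freqs <= band[2]
  df <- diff(spec$freqs[1:2])
  tibble::tibble(
    time = spec$times,
    value = rowSums(spec$power[, cols, drop = FALSE]) * df
  )
}

#' Baseline-normalized event-triggered traces
#'
#' Extracts, for every event, the signal from `baseline` seconds before
#' onset to the event offset (plus `post` seconds), divided by that event's
#' own pre-onset mean, so 1 means no change. Events without a full baseline
#' are skipped with a warning.
#'
#' @param power Time-series tibble (e.g. gamma-band power).
#' @param events Event tibble with `onset` and `offset` columns.
#' @param baseline Pre-onset normalization window, s.
#' @param post Extra time beyond the event offset, s.
#' @return Tibble with columns `event`, `time` (relative to onset), `value`.
#' @export
evoked_normalize <- function(power, events, baseline = 3, post = 0) {
  tm <- ts_time(power)
  v <- ts_values(power)
  rate <- ts_rate(power)
  out <- purrr::map_dfr(seq_len(nrow(events)), function(e) {
    on <- events$onset[e]
    off <- events$offset[e] + post
    pre <- tm >= on - baseline & tm < on
    if (sum(pre) < max(1, floor(0.9 * baseline * rate)) || tm[1] > on - baseline) {
      warning(sprintf("event %d lacks %g s of pre-onset data; skipped", e, baseline))
      return(NULL)
    }
    b <- mean(v[pre])
    win <- tm >= on - baseline & tm <= off
    tibble::tibble(event = e, time = tm[win] - on, value = v[win] / b)
  })
  out
}

robust_sd <- function(x) stats::mad(x, constant = 1.4826)

#' MUA spike rate
#'
#' Counts threshold crossings (`k_sd` robust standard deviations above the
#' background, estimated by the median absolute deviation) in 1 ms bins and
#' smooths the resulting rate with a zero-phase Bessel low-pass.
#'
#' @param mua Time-series tibble of the 300-3000 Hz band.
#' @param k_sd Threshold in background SDs.
#' @param bin Bin width, s.
#' @param smooth Bessel low-pass cutoff, Hz (`NULL` disables smoothing).
#' @return Time-series tibble of spike rate (Hz) at `1/bin` resolution.
#' @export
spike_rate <- function(mua, k_sd = 3, bin = 0.001, smooth = 5) {
  v <- ts_values(mua)
  rate <- ts_rate(mua)
  sdv <- robust_sd(v)
  if (sdv == 0) stop("zero-variance signal: no background to threshold", call. = FALSE)
  thr <- stats::median(v) + k_sd * sdv
  up <- which(v[-1L] > thr & v[-length(v)] <= thr) + 1L
  tm <- ts_time(mua)
  edges <- seq(tm[1], tm[length(tm)] + bin, by = bin)
  counts <- graphics::hist(tm[up], breaks = edges, plot = FALSE)$counts
  out <- ts_new(counts / bin, rate = 1 / bin, t0 = tm[1] + bin / 2, units = "Hz")
  if (!is.null(smooth)) {
    out$value <- bessel_zp(out$value, 1 / bin, smooth, order = 4)
  }
  out
}

# Biphasic spike template: positive peak at 0 and trough `ptt_ms` later,
# rescaled so the measured peak-to-trough distance equals `ptt_ms` exactly.
spike_template <- function(ptt_ms, rate, trough_frac = 0.55) {
  shape <- function(t, p) exp(-(t / (0.25 * p))^2 / 2) -
    trough_frac * exp(-((t - p) / (0.45 * p))^2 / 2)
  tt <- seq(-2 * ptt_ms, 4 * ptt_ms, by = 1e-3) # ms grid for calibration
  w <- shape(tt, ptt_ms)
  meas <- tt[which.min(w)] - tt[which.max(w)]
  p_adj <- ptt_ms * ptt_ms / meas
  t_s <- seq(-1.5 * ptt_ms, 3 * ptt_ms, by = 1000 / rate) # ms
  val <- shape(t_s, p_adj)
  list(t_ms = t_s, values = val / max(val))
}

#' Classify spike waveforms as fast-spiking or regular-spiking
#'
#' Extracts waveforms at `k_sd`-SD threshold crossings, upsamples them with a
#' cubic spline, normalizes to unit peak amplitude and measures each spike's
#' peak-to-trough duration. The duration histogram (0.05 ms bins) is fitted
#' with a two-Gaussian mixture by EM; bins whose posterior membership in a
#' component reaches `post_min` are labelled FS (short durations) or RS
#' (long durations), the rest stay unclassified. Labels are forced to be
#' monotone in duration: a single boundary separates the two classes.
#'
#' When the fitted components are closer than 0.2 ms or one of them is a
#' vestigial outlier-absorber (weight < 0.08), the data are treated as a
#' single duration regime: everything is labelled FS if the mean duration
#' is below 0.4 ms, RS above 0.6 ms, and left unclassified in the
#' ambiguous middle where the regime cannot be named.
#'
#' @param mua Time-series tibble of the 300-3000 Hz band.
#' @param k_sd Detection threshold in robust background SDs.
#' @param bin_ms Histogram bin width, ms.
#' @param post_min Posterior probability required for a label.
#' @param upsample Spline upsampling factor before peak localization.
#' @param restarts EM restarts with jittered initialization.
#' @param seed Seed for the EM restarts.
#' @return An object of class `ox_spikeset`: `spikes` tibble
#'   (`time`, `ptt`, `label`), normalized `waveforms` matrix, and the fitted
#'   `mixture` (means, sds, weights, boundary).
#' @export
classify_fs_rs <- function(mua, k_sd = 4, bin_ms = 0.05, post_min = 0.95,
                           upsample = 10, restarts = 10, seed = 1) {
  v <- ts_values(mua)
  rate <- ts_rate(mua)
  tm <- ts_time(mua)
  sdv <- robust_sd(v)
  if (sdv == 0) stop("zero-variance signal", call. = FALSE)
  thr <- stats::median(v) + k_sd * sdv
  up <- which(v[-1L] > thr & v[-length(v)] <= thr) + 1L
  refr <- round(0.001 * rate) # 1 ms refractory between detections
  if (length(up) > 1L) up <- up[c(TRUE, diff(up) > refr)]
  pre <- round(0.0005 * rate)
  post <- round(0.0015 * rate)
  up <- up[up > pre + refr & up < length(v) - post - refr]
  if (length(up) < 200L) {
    stop("need at least 200 detected spikes for a stable mixture fit", call. = FALSE)
  }
  # align on the local peak after the crossing
  peak_at <- vapply(up, function(i) i - 1L + which.max(v[i:(i + refr)]), integer(1))
  wf <- t(vapply(
    peak_at,
    function(i) v[(i - pre):(i + post)], numeric(pre + post + 1L)
  ))
  # spline-upsample, peak-normalize, measure peak-to-trough duration
  t_ms <- (seq_len(ncol(wf)) - 1 - pre) / rate * 1000
  t_fine <- seq(t_ms[1], t_ms[length(t_ms)], length.out = upsample * length(t_ms))
  ptt <- numeric(nrow(wf))
  wnorm <- matrix(0, nrow(wf), length(t_fine))
  for (i in seq_len(nrow(wf))) {
    sp <- stats::spline(t_ms, wf[i, ], xout = t_fine)$y
    pk <- which.max(sp)
    sp <- sp / sp[pk]
    wnorm[i, ] <- sp
    tr <- pk - 1L + which.min(sp[pk:length(sp)])
    ptt[i] <- t_fine[tr] - t_fine[pk]
  }
  keep <- ptt > 0
  fit <- fit_ptt_mixture(ptt[keep], bin_ms, restarts, seed)
  label <- rep("unclassified", length(ptt))
  if (fit$collapsed) {
    # one duration regime only: name it by its absolute duration, or leave
    # everything unclassified when it sits between the FS and RS regimes
    m <- stats::weighted.mean(fit$mu, fit$weights)
    if (m <= 0.4) {
      label[keep] <- "FS"
    } else if (m >= 0.6) {
      label[keep] <- "RS"
    }
  } else {
    post_fs <- ptt_posterior(ptt, fit)
    label[keep & ptt <= fit$boundary & post_fs >= post_min] <- "FS"
    label[keep & ptt >= fit$boundary & (1 - post_fs) >= post_min] <- "RS"
  }
  structure(
    list(
      spikes = tibble::tibble(time = tm[peak_at], ptt = ptt, label = label),
      waveforms = wnorm,
      t_ms = t_fine,
      mixture = fit
    ),
    class = "ox_spikeset"
  )
}

# Weighted EM for a two-Gaussian mixture on the binned duration histogram.
fit_ptt_mixture <- function(ptt, bin_ms, restarts, seed) {
  br <- seq(0, max(ptt) + bin_ms, by = bin_ms)
  h <- graphics::hist(ptt, breaks = br, plot = FALSE)
  x <- h$mids
  w <- h$counts
  use <- w > 0
  x <- x[use]
  w <- w[use]
  em_run <- function(mu0) {
    mu <- mu0
    sg <- rep(max(bin_ms, stats::sd(rep(x, w)) / 2), 2)
    pw <- c(0.5, 0.5)
    ll_old <- -Inf
    for (it in 1:500) {
      d1 <- pw[1] * stats::dnorm(x, mu[1], sg[1])
      d2 <- pw[2] * stats::dnorm(x, mu[2], sg[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      g <- d1 / tot
      n1 <- sum(w * g)
      n2 <- sum(w * (1 - g))
      if (n1 < 1e-8 || n2 < 1e-8) break
      mu <- c(sum(w * g * x) / n1, sum(w * (1 - g) * x) / n2)
      sg <- sqrt(c(
        sum(w * g * (x - mu[1])^2) / n1,
        sum(w * (1 - g) * (x - mu[2])^2) / n2
      ))
      sg <- pmax(sg, bin_ms / 4)
      pw <- c(n1, n2) / (n1 + n2)
      ll <- sum(w * log(tot))
      if (abs(ll - ll_old) < 1e-10) break
      ll_old <- ll
    }
    list(mu = mu, sg = sg, pw = pw, ll = ll_old)
  }
  qs <- stats::quantile(rep(x, w), c(0.25, 0.75), names = FALSE)
  inits <- c(list(qs), with_seed(seed, replicate(restarts,
    sort(sample(rep(x, w), 2)) + stats::rnorm(2, 0, bin_ms),
    simplify = FALSE
  )))
  fits <- lapply(inits, em_run)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
  ord <- order(best$mu)
  mu <- best$mu[ord]
  sg <- best$sg[ord]
  pw <- best$pw[ord]
  if (any(!is.finite(c(mu, sg, pw)))) {
    stop("mixture fit degenerate: classification aborted", call. = FALSE)
  }
  # single-regime data: components closer than any real FS/RS separation, or
  # one component reduced to a vestigial outlier-absorber
  collapsed <- (mu[2] - mu[1]) < 0.2 || min(pw) < 0.08
  boundary <- NA_real_
  if (!collapsed) {
    f <- function(t) {
      pw[1] * stats::dnorm(t, mu[1], sg[1]) - pw[2] * stats::dnorm(t, mu[2], sg[2])
    }
    boundary <- tryCatch(
      stats::uniroot(f, c(mu[1], mu[2]), tol = 1e-8)$root,
      error = function(e) mean(mu)
    )
  }
  list(
    mu = mu, sg = sg, weights = pw, loglik = best$ll,
    collapsed = collapsed, boundary = boundary, bin_ms = bin_ms
  )
}

# Posterior probability that a duration belongs to the FS (short) component.
ptt_posterior <- function(ptt, fit) {
  d1 <- fit$weights[1] * stats::dnorm(ptt, fit$mu[1], fit$sg[1])
  d2 <- fit$weights[2] * stats::dnorm(ptt, fit$mu[2], fit$sg[2])
  d1 / pmax(d1 + d2, .Machine$double.xmin)
}

#' @export
tidy.ox_spikeset <- function(x, ...) x$spikes

#' @export
glance.ox_spikeset <- function(x, ...) {
  tibble::tibble(
    n_spikes = nrow(x$spikes),
    n_fs = sum(x$spikes$label == "FS"),
    n_rs = sum(x$spikes$label == "RS"),
    n_unclassified = sum(x$spikes$label == "unclassified"),
    mu_fs = x$mixture$mu[1], mu_rs = x$mixture$mu[2],
    boundary = x$mixture$boundary
  )
}

#' @export
print.ox_spikeset <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<ox_spikeset> %d spikes: %d FS, %d RS, %d unclassified (boundary %.3g ms)\n",
    g$n_spikes, g$n_fs, g$n_rs, g$n_unclassified, g$boundary
  ))
  invisible(x)
}

#' @export
autoplot.ox_spikeset <- function(object, ...) {
  ggplot2::ggplot(object$spikes, ggplot2::aes(x = .data$ptt, fill = .data$label)) +
    ggplot2::geom_histogram(binwidth = object$mixture$bin_ms, boundary = 0) +
    ggplot2::labs(x = "peak-to-trough duration (ms)", y = "spikes") +
    ggplot2::theme_minimal()
}
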