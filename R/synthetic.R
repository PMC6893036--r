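# Synthetic multimodal session generator with configurable ground truth.
#
# The generator emulates the statistical structure the analysis stages
# assume -- Poisson-arriving locomotion bouts, 1/f LFP with state-dependent
# gamma power, template spikes on noise, a kernel-convolved tissue-oxygen
# trace with a respiration-coupled component, a raised-cosine thermocouple
# breath train, Beer-Lambert forward-mapped reflectance frames, and
# Stern-Volmer phosphorescence decays -- so every downstream operation can
# be validated against known truth without any recording.

#' Gamma-variate response kernel
#'
#' Convenience ground-truth kernel for the generator: a smooth single-lobe
#' impulse response with a given peak time and amplitude.
#'
#' @param peak_time Lag of the peak, s.
#' @param duration Kernel support, s.
#' @param amplitude Peak amplitude (signal units per unit locomotion).
#' @param rate Sampling rate of the lag grid, Hz.
#' @param shape Gamma shape parameter (larger = more symmetric).
#' @return Tibble with `lag` and `value`.
#' @export
make_hrf <- function(peak_time = 4, duration = 12, amplitude = 3,
                     rate = 30, shape = 3) {
  lag <- seq(0, duration, by = 1 / rate)
  tau <- peak_time / (shape - 1)
  v <- lag^(shape - 1) * exp(-lag / tau)
  v <- v / max(v) * amplitude
  tibble::tibble(lag = lag, value = v)
}

#' Generator configuration
#'
#' Study-condition defaults for [generate_session()]: channel rates mirror
#' the acquisition described for head-fixed mice on a spherical treadmill
#' (1 kHz analog channels, 20 kHz multiunit band, 30 Hz frames), locomotion
#' bouts arrive as a Poisson process with exponential durations, and the
#' ground-truth response kernels, gamma-power gain, respiration rates and
#' arterial-oxygen modulation depth are all explicit.
#'
#' @param duration_s Session length, s (>= 60).
#' @param velocity_rate,pto2_rate,thermo_rate,lfp_rate,mua_rate,frame_rate
#'   Channel sampling rates, Hz.
#' @param bout_rate Locomotion bout arrivals per second (Poisson).
#' @param bout_mean,bout_min Bout duration: `bout_min` plus an exponential
#'   of mean `bout_mean - bout_min`, s.
#' @param gap_min Minimum enforced inter-bout gap, s.
#' @param hrf Ground-truth oxygen response kernel (tibble `lag`, `value`)
#'   sampled at `pto2_rate`; default [make_hrf()].
#' @param gamma_gain_loco Multiplicative gamma-power gain during bouts.
#' @param resp_rate_rest,resp_rate_loco Respiratory rates, Hz.
#' @param resp_modulation_depth Peak-to-trough arterial oxygen swing over a
#'   respiratory cycle, mmHg.
#' @param resp_coupling Amplitude of the respiration-coupled tissue-oxygen
#'   component, mmHg.
#' @param pao2_baseline Resting arterial oxygen tension, mmHg.
#' @param fs_fraction Fraction of spikes from the fast-spiking template.
#' @param fs_ptt,rs_ptt Template peak-to-trough durations, ms.
#' @param ptt_jitter Per-spike duration jitter SD, ms.
#' @param mua_rate_rest Resting multiunit event rate, Hz.
#' @param mua_gain_loco Multiplicative rate gain during bouts.
#' @param spike_amp Spike amplitude in units of the MUA noise SD.
#' @param noise Named list of channel noise SDs.
#' @return Configuration list of class `ox_config`.
#' @export
session_config <- function(duration_s = 300,
                           velocity_rate = 1000, pto2_rate = 1000,
                           thermo_rate = 1000, lfp_rate = 1000,
                           mua_rate = 20000, frame_rate = 30,
                           bout_rate = 1 / 45, bout_mean = 8, bout_min = 2,
                           gap_min = 8,
                           hrf = NULL,
                           gamma_gain_loco = 2,
                           resp_rate_rest = 2.5, resp_rate_loco = 5,
                           resp_modulation_depth = 5, resp_coupling = 0.3,
                           pao2_baseline = 35,
                           fs_fraction = 0.5, fs_ptt = 0.3, rs_ptt = 0.7,
                           ptt_jitter = 0.05,
                           mua_rate_rest = 8, mua_gain_loco = 2,
                           spike_amp = 8,
                           noise = list(
                             velocity = 0.02, pto2 = 0.5,
                             lfp = 1, mua = 1, thermo = 0.01,
                             frame = 5e-4
                           )) {
  cfg <- as.list(environment())[names(formals(session_config))]
  if (duration_s < 60) stop("configure at least 60 s of data", call. = FALSE)
  if (any(c(velocity_rate, pto2_rate, thermo_rate, lfp_rate, mua_rate, frame_rate) <= 0)) {
    stop("channel rates must be positive", call. = FALSE)
  }
  if (any(c(resp_rate_rest, resp_rate_loco) <= 0)) {
    stop("respiratory rates must be positive", call. = FALSE)
  }
  if (resp_modulation_depth < 0) stop("modulation depth must be >= 0", call. = FALSE)
  if (fs_fraction < 0 || fs_fraction > 1) stop("fs_fraction must lie in [0, 1]", call. = FALSE)
  cfg$hrf <- hrf %||% make_hrf(rate = pto2_rate)
  structure(cfg, class = "ox_config")
}

# Poisson bout train: onset/offset tibble within [0, duration].
draw_bouts <- function(cfg) {
  t <- 0
  on <- off <- numeric()
  repeat {
    gap <- cfg$gap_min + stats::rexp(1, cfg$bout_rate)
    dur <- cfg$bout_min + stats::rexp(1, 1 / (cfg$bout_mean - cfg$bout_min))
    if (t + gap + dur > cfg$duration_s - 5) break
    on <- c(on, t + gap)
    off <- c(off, t + gap + dur)
    t <- t + gap + dur
  }
  tibble::tibble(onset = on, offset = off)
}

# zero-padded causal convolution: y[t] = sum_j h[j] x[t - j + 1]
conv_causal <- function(x, h) {
  p <- length(h)
  y <- stats::filter(c(rep(0, p - 1), x), h, method = "convolution", sides = 1)
  as.numeric(y)[p:(p + length(x) - 1)]
}

loco_indicator <- function(bouts, rate, duration) {
  n <- round(duration * rate)
  tm <- (seq_len(n) - 1) / rate
  d <- integer(n)
  for (b in seq_len(nrow(bouts))) {
    d[tm >= bouts$onset[b] & tm < bouts$offset[b]] <- 1L
  }
  list(time = tm, delta = d)
}

# Velocity trace whose 10 Hz-filtered |acceleration| stays above the 3
# cm/s^2 threshold inside bouts (alternating stride accelerations) and
# below it outside.
synth_velocity <- function(cfg, bouts) {
  rate <- cfg$velocity_rate
  ind <- loco_indicator(bouts, rate, cfg$duration_s)
  accel <- rep(0, length(ind$delta))
  stride <- round(0.25 * rate) # half-period of the stride acceleration
  phase <- (seq_along(accel) - 1) %/% stride %% 2
  accel[ind$delta == 1L] <- ifelse(phase[ind$delta == 1L] == 0, 12, -12)
  v <- numeric(length(accel))
  for (i in seq_along(v)[-1]) {
    v[i] <- if (ind$delta[i] == 1L) {
      max(0, v[i - 1] + accel[i] / rate)
    } else {
      max(0, v[i - 1] - 1.5 / rate) # gentle sub-threshold relaxation
    }
  }
  v <- v + stats::rnorm(length(v), 0, cfg$noise$velocity)
  ts_new(v, rate, units = "cm/s")
}

# 1/f LFP whose 40-100 Hz component is scaled by sqrt(gain) during bouts.
synth_lfp <- function(cfg, bouts) {
  rate <- cfg$lfp_rate
  n <- round(cfg$duration_s * rate)
  f <- seq(0, rate - rate / n, by = rate / n)
  f_fold <- pmin(f, rate - f)
  amp <- 1 / sqrt(pmax(f_fold, 0.5))
  spec <- amp * (stats::rnorm(n) + 1i * stats::rnorm(n))
  x <- Re(stats::fft(spec, inverse = TRUE)) / sqrt(n)
  in_gamma <- f_fold >= 40 & f_fold <= 100
  spec_g <- spec
  spec_g[!in_gamma] <- 0
  g <- Re(stats::fft(spec_g, inverse = TRUE)) / sqrt(n)
  base <- x - g
  ind <- loco_indicator(bouts, rate, cfg$duration_s)
  gain_t <- ifelse(ind$delta == 1L, sqrt(cfg$gamma_gain_loco), 1)
  v <- base + gain_t * g + stats::rnorm(n, 0, cfg$noise$lfp * 1e-3)
  v <- v / stats::sd(v) * cfg$noise$lfp
  ts_new(v, rate, units = "a.u.")
}

synth_mua <- function(cfg, bouts) {
  rate <- cfg$mua_rate
  n <- round(cfg$duration_s * rate)
  v <- stats::rnorm(n, 0, cfg$noise$mua)
  ind <- loco_indicator(bouts, rate, cfg$duration_s)
  lam <- cfg$mua_rate_rest * ifelse(ind$delta == 1L, cfg$mua_gain_loco, 1) / rate
  spikes_at <- which(stats::runif(n) < lam)
  # enforce 3 ms separation so waveforms do not overlap
  if (length(spikes_at) > 1L) {
    spikes_at <- spikes_at[c(TRUE, diff(spikes_at) > 0.003 * rate)]
  }
  is_fs <- stats::runif(length(spikes_at)) < cfg$fs_fraction
  truth_sp <- tibble::tibble(
    time = (spikes_at - 1) / rate,
    kind = ifelse(is_fs, "FS", "RS")
  )
  for (s in seq_along(spikes_at)) {
    ptt <- max(0.12, (if (is_fs[s]) cfg$fs_ptt else cfg$rs_ptt) +
      stats::rnorm(1, 0, cfg$ptt_jitter))
    tpl <- spike_template(ptt, rate)
    amp <- cfg$spike_amp * cfg$noise$mua * stats::runif(1, 0.9, 1.1)
    i0 <- spikes_at[s] + round(tpl$t_ms[1] * rate / 1000)
    idx <- i0 + seq_along(tpl$values) - 1L
    ok <- idx >= 1L & idx <= n
    v[idx[ok]] <- v[idx[ok]] + amp * tpl$values[ok]
  }
  list(ts = ts_new(v, rate, units = "a.u."), spikes = truth_sp)
}

# Respiration phase (cycles) and thermocouple waveform.
synth_resp <- function(cfg, bouts) {
  rate <- cfg$thermo_rate
  ind <- loco_indicator(bouts, rate, cfg$duration_s)
  inst <- ifelse(ind$delta == 1L, cfg$resp_rate_loco, cfg$resp_rate_rest)
  inst <- butter_zp(inst, rate, 0.5, 2, "low") # smooth rate transitions
  phase <- cumsum(inst) / rate # cycles
  w <- ((1 + cos(2 * pi * phase)) / 2)^2
  peaks <- ind$time[diff(c(0, floor(phase))) >= 1] # phase crossing integers
  list(
    ts = ts_new(w + stats::rnorm(length(w), 0, cfg$noise$thermo),
      rate,
      units = "a.u."
    ),
    phase = phase, peaks = peaks, inst_rate = inst, time = ind$time
  )
}

synth_pto2 <- function(cfg, bouts, resp) {
  rate <- cfg$pto2_rate
  ind <- loco_indicator(bouts, rate, cfg$duration_s)
  conv <- conv_causal(ind$delta, cfg$hrf$value) / rate # kernel per locomotion-second
  ph <- stats::approx(resp$time, resp$phase, ind$time, rule = 2)$y
  resp_term <- cfg$resp_coupling * sin(2 * pi * ph)
  v <- cfg$pao2_baseline + conv + resp_term +
    stats::rnorm(length(conv), 0, cfg$noise$pto2)
  list(ts = ts_new(v, rate, units = "mmHg"), delta = ind$delta, response = conv)
}

synth_reflectance <- function(cfg, bouts, npix = 16) {
  rate <- cfg$frame_rate
  ind <- loco_indicator(bouts, rate, cfg$duration_s)
  k_hbo <- make_hrf(peak_time = 2, duration = 8, amplitude = 8, rate = rate)
  k_hbr <- make_hrf(peak_time = 3, duration = 10, amplitude = -4, rate = rate)
  cv <- function(k) conv_causal(ind$delta, k$value) / rate
  hemo <- tibble::tibble(time = ind$time, dHbO = cv(k_hbo), dHbR = cv(k_hbr))
  dr <- beer_lambert_forward(hemo, wavelengths = c(530, 470))
  frames <- lapply(c("530", "470"), function(wl) {
    base <- 1 + dr[[wl]] / 100
    m <- matrix(rep(base, npix), ncol = npix)
    m * (1 + matrix(stats::rnorm(length(m), 0, cfg$noise$frame), ncol = npix))
  })
  names(frames) <- c("530", "470")
  list(
    stack = reflectance_stack(frames, rate),
    hemo = hemo
  )
}

#' Generate a synthetic multimodal session
#'
#' Draws a full session (velocity, LFP, MUA, tissue oxygen, thermocouple,
#' two-wavelength reflectance) with the configured ground truth. Identical
#' `config` and `seed` give bit-identical sessions. Phosphorescence decays
#' are generated separately with [generate_decays()] because their volume is
#' usage-dependent.
#'
#' @param config A [session_config()].
#' @param seed Integer seed.
#' @param channels Channels to generate (subset of
#'   `c("velocity", "lfp", "mua", "pto2", "thermocouple", "reflectance")`).
#' @return Object of class `ox_session`: the requested channels plus a
#'   `truth` list (bouts, locomotion indicator at the oxygen rate, the true
#'   kernel, spike times/classes, respiration peaks and phase, imposed
#'   hemoglobin time courses).
#' @export
#' @examples
#' s <- generate_session(session_config(duration_s = 60), seed = 1)
#' names(s)
generate_session <- function(config = session_config(), seed,
                             channels = c(
                               "velocity", "lfp", "mua", "pto2",
                               "thermocouple", "reflectance"
                             )) {
  stopifnot(inherits(config, "ox_config"))
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  with_seed(seed, {
    bouts <- draw_bouts(config)
    out <- list(truth = list(
      bouts = bouts, hrf = config$hrf, seed = seed,
      config = config
    ))
    resp <- synth_resp(config, bouts)
    if ("velocity" %in% channels) out$velocity <- synth_velocity(config, bouts)
    if ("lfp" %in% channels) out$lfp <- synth_lfp(config, bouts)
    if ("mua" %in% channels) {
      m <- synth_mua(config, bouts)
      out$mua <- m$ts
      out$truth$spikes <- m$spikes
    }
    if ("pto2" %in% channels) {
      p <- synth_pto2(config, bouts, resp)
      out$pto2 <- p$ts
      out$truth$delta_pto2 <- tibble::tibble(
        time = ts_time(p$ts), delta = p$delta
      )
      out$truth$pto2_response <- p$response
    }
    if ("thermocouple" %in% channels) {
      out$thermocouple <- resp$ts
      out$truth$resp_peaks <- resp$peaks
      out$truth$resp_rate <- tibble::tibble(time = resp$time, value = resp$inst_rate)
    }
    if ("reflectance" %in% channels) {
      rf <- synth_reflectance(config, bouts)
      out$reflectance <- rf$stack
      out$truth$hemo <- rf$hemo
    }
    structure(out, class = "ox_session")
  })
}

#' @export
print.ox_session <- function(x, ...) {
  chans <- setdiff(names(x), "truth")
  cat(sprintf(
    "<ox_session> %g s | channels: %s | %d locomotion bouts (seed %d)\n",
    x$truth$config$duration_s, paste(chans, collapse = ", "),
    nrow(x$truth$bouts), x$truth$seed
  ))
  invisible(x)
}

#' Generate phosphorescence decay records
#'
#' Draws Poisson photon-count decays whose instantaneous lifetime follows
#' the Stern-Volmer map of an arterial oxygen trace plus a sinusoidal
#' respiration-phase modulation (peak-to-trough `modulation_depth`, maximum
#' a quarter cycle after the expiratory peak). Timestamps cover the trace
#' uniformly at `rep_rate`.
#'
#' @param pao2_trace Time-series tibble of baseline arterial oxygen, mmHg.
#' @param resp_peaks Expiratory peak times, s (may be empty when
#'   `modulation_depth = 0`).
#' @param modulation_depth Peak-to-trough oxygen swing per cycle, mmHg.
#' @param calib An [oximetry_calibration()].
#' @param seed Integer seed.
#' @param rep_rate Decay acquisitions per second.
#' @param record_us Record length per decay, us.
#' @param rate Digitization rate, Hz.
#' @param amp Expected peak photon signal per decay, counts.
#' @param background Expected background, counts.
#' @param shot_noise Draw Poisson counts (`TRUE`) or return noiseless
#'   expectations.
#' @return An [decay_set()] object; attribute `true_po2` stores each decay's
#'   instantaneous oxygen tension.
#' @export
generate_decays <- function(pao2_trace, resp_peaks, modulation_depth = 5,
                            calib = oximetry_calibration(), seed = 1,
                            rep_rate = 1000, record_us = 200, rate = 1.25e6,
                            amp = 50, background = 2, shot_noise = TRUE) {
  if (modulation_depth > 0 && length(resp_peaks) == 0L) {
    stop("respiration peaks required when modulation depth is non-zero", call. = FALSE)
  }
  tm <- ts_time(pao2_trace)
  with_seed(seed, {
    t_d <- seq(tm[1], tm[length(tm)], by = 1 / rep_rate)
    base <- stats::approx(tm, ts_values(pao2_trace), t_d, rule = 2)$y
    mod <- rep(0, length(t_d))
    if (modulation_depth > 0) {
      pk <- sort(resp_peaks)
      cyc <- diff(pk)
      idx <- pmin(pmax(findInterval(t_d, pk), 1L), length(cyc))
      frac <- (t_d - pk[idx]) / cyc[idx]
      mod <- (modulation_depth / 2) * sin(2 * pi * frac)
    }
    po2 <- pmax(base + mod, 0.1)
    tau <- stern_volmer_tau(po2, calib) # us
    ns <- round(record_us * 1e-6 * rate)
    t_s <- (seq_len(ns) - 1) / rate * 1e6 # us
    expect <- amp * exp(outer(-1 / tau, t_s)) + background
    counts <- if (shot_noise) {
      matrix(stats::rpois(length(expect), expect), nrow = nrow(expect))
    } else {
      expect
    }
    ds <- decay_set(t_d, counts, rate = rate)
    attr(ds, "true_po2") <- po2
    ds
  })
}
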