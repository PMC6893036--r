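test_that("expiratory peaks and instantaneous rate are recovered from a breath train", {
  # pure 2.5 Hz sinusoid: peaks every 0.4 s, rate identically 2.5 Hz
  th <- tone(2.5, 1000, 20, phase = pi / 2) # cosine: first peak at t = 0
  r <- detect_expiratory_peaks(th)
  expect_equal(diff(r$peaks), rep(0.4, length(r$peaks) - 1), tolerance = 5e-3)
  expect_equal(mean(r$rate$value), 2.5, tolerance = 0.01)

  # rate-modulated synthetic breathing tracks the configured rate
  s <- quick_session(seed = 81, duration = 120)
  rr <- detect_expiratory_peaks(bandpass(s$thermocouple, 0, 15))
  truth <- s$truth$resp_rate
  est <- stats::approx(rr$rate$time, rr$rate$value, truth$time, rule = 2)$y
  steady <- abs(truth$value - 2.5) < 0.01 | abs(truth$value - 5) < 0.01
  expect_lt(mean(abs(est[steady] - truth$value[steady]) / truth$value[steady]), 0.05)

  expect_error(detect_expiratory_peaks(ts_new(rep(1, 1000), 100)), "peaks")
})

test_that("regular-respiration selection applies the SD and ratio criteria", {
  const <- ts_new(rep(2.5, 300), rate = 10)
  rf <- regularity_filter(const)
  expect_true(all(rf$accepted))

  withr::with_seed(82, {
    noisy <- ts_new(pmin(2.5 + stats::rnorm(300, 0, 0.8), 4.9), rate = 10)
    rn <- regularity_filter(noisy)
    expect_false(any(rn$accepted)) # SD 0.8 > 0.6

    mid <- ts_new(2.5 + stats::rnorm(300, 0, 0.45), rate = 10)
    rm <- regularity_filter(mid) # SD ~0.45, ratio ~5.5 > 4
    expect_true(mean(rm$accepted) > 0.5)
  })
  expect_error(regularity_filter(tibble::tibble(time = numeric(), value = numeric())))
})

test_that("lifetime fitting recovers oxygen tension through the Stern-Volmer map", {
  cal <- oximetry_calibration()
  # exact zero-oxygen limit of the map itself
  expect_equal(stern_volmer_po2(cal$tau0, cal), 0)
  expect_equal(stern_volmer_po2(stern_volmer_tau(35, cal), cal), 35)
  # strictly decreasing in lifetime
  taus <- seq(10, cal$tau0, length.out = 20)
  expect_true(all(diff(stern_volmer_po2(taus, cal)) < 0))

  # noiseless decays at the 35 mmHg lifetime
  d0 <- generate_decays(flat_pao2(10), numeric(0), 0, cal,
    seed = 1,
    rep_rate = 300, shot_noise = FALSE
  )
  po <- lifetime_to_po2(d0, group = 100, cal)
  expect_equal(unique(round(po$value, 2)), 35)

  # shot noise: grouped estimates unbiased within 2 SEM
  reps <- vapply(1:30, function(s) {
    d <- generate_decays(flat_pao2(8), numeric(0), 0, cal,
      seed = s, rep_rate = 400
    )
    lifetime_to_po2(d, group = 3000, cal)$value[1]
  }, numeric(1))
  expect_lt(abs(mean(reps) - 35), 2 * stats::sd(reps) / sqrt(length(reps)) + 0.05)

  expect_error(oximetry_calibration(tau0 = -1), "positive")
  expect_error(
    lifetime_to_po2(decay_set(1:2, matrix(1, 2, 100)), group = 3000),
    "fewer decays"
  )
})

test_that("phase alignment pools decays into 20 ms bins and conserves counts", {
  cal <- oximetry_calibration()
  peaks <- regular_peaks(20)
  dec <- generate_decays(flat_pao2(20), peaks, 5, cal, seed = 83, rep_rate = 800)
  prof <- phase_align(dec, peaks, bin = 0.02, calib = cal)
  # 0.4 s cycle at 20 ms bins: exactly 20 bins
  expect_equal(nrow(prof), 20)
  # pooled counts equal the decays inside complete cycles, phase < 20 bins
  ts_d <- dec$timestamps
  inside <- ts_d >= peaks[1] & ts_d < peaks[length(peaks)]
  phase <- ts_d[inside] - peaks[findInterval(ts_d[inside], peaks)]
  expect_equal(sum(prof$count), sum(phase < 20 * 0.02))

  # sinusoidal 5 mmHg modulation appears with near-true amplitude
  ext <- tmin_tmax(prof)
  expect_equal(ext$pao2_max - ext$pao2_min, 5, tolerance = 1.5)
  expect_gte(ext$pao2_max, ext$pao2_min)

  # zero modulation: flat profile within noise. The per-bin SE of the
  # pooled three-parameter fit is ~2.5x the ideal decay-averaging bound
  # (the free background costs precision), so allow 6 x that.
  dec0 <- generate_decays(flat_pao2(20), peaks, 0, cal, seed = 84, rep_rate = 800)
  prof0 <- phase_align(dec0, peaks, calib = cal)
  bin_se <- 2.5 * stats::sd(attr(prof0, "decay_po2")$po2) / sqrt(mean(prof0$count))
  expect_lt(max(prof0$pao2) - min(prof0$pao2), 6 * bin_se)
})

test_that("binomial smoothing has unit DC gain and the exact impulse/sinusoid response", {
  expect_equal(binomial_smooth(rep(3.3, 12)), rep(3.3, 12))

  # impulse response after five passes: 10th-order binomial kernel / 2^10
  imp <- c(1, rep(0, 19))
  sm <- binomial_smooth(imp, reps = 5)
  expect_equal(sort(sm, decreasing = TRUE)[1], choose(10, 5) / 2^10)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  kern <- choose(10, 0:10) / 2^10
  expect_equal(sm[1:6], kern[6:11]) # right half of the centred kernel

  # sinusoid over 20 circular bins: attenuation cos^10(pi/20), no phase shift
  x <- sin(2 * pi * (0:19) / 20)
  smx <- binomial_smooth(x, reps = 5)
  expect_equal(smx, cos(pi / 20)^10 * x, tolerance = 1e-12)

  expect_error(binomial_smooth(c(1, 2)), "3 bins")
})

test_that("extremal windows sit half a cycle apart on sinusoidal profiles", {
  prof <- tibble::tibble(
    bin_time = (1:20 - 0.5) * 0.02,
    pao2 = 35 + 2.5 * sin(2 * pi * (1:20 - 0.5) / 20),
    count = rep(100, 20)
  )
  prof$smoothed <- binomial_smooth(prof$pao2)
  attr(prof, "bin") <- 0.02
  class(prof) <- c("ox_cycleprofile", class(prof))
  ext <- tmin_tmax(prof)
  sep <- abs(ext$tmax - ext$tmin)
  expect_equal(min(sep, 0.4 - sep), 0.2, tolerance = 0.021)

  # circular monotone ramp: extremes adjacent across the wrap point
  ramp <- prof
  ramp$pao2 <- 30 + (1:20) / 4
  ramp$smoothed <- binomial_smooth(ramp$pao2)
  er <- tmin_tmax(ramp)
  dist <- abs(er$tmax - er$tmin)
  expect_lt(min(dist, 0.4 - dist), 0.1)

  flat <- prof
  flat$pao2 <- rep(35, 20)
  flat$smoothed <- rep(35, 20)
  expect_warning(tmin_tmax(flat), "flat")
})

test_that("the respiration-locked permutation test converges across surrogate counts", {
  cal <- oximetry_calibration()
  peaks <- regular_peaks(25)
  dec <- generate_decays(flat_pao2(25), peaks, 6, cal, seed = 85, rep_rate = 900)
  prof <- phase_align(dec, peaks, calib = cal)
  t1 <- respiration_locked_test(prof, n_surrogates = 1000, seed = 1)
  t2 <- respiration_locked_test(prof, n_surrogates = 4000, seed = 2)
  expect_true(t1$significant)
  expect_equal(t1$significant, t2$significant)
  expect_equal(t1$peak_freq, 2.5)
  expect_error(
    respiration_locked_test(prof, resp_freq = 40, n_surrogates = 1000),
    "outside"
  )
})

test_that("paired extremal oxygen values support exact inference across recordings", {
  cal <- oximetry_calibration()
  peaks <- regular_peaks(15)
  ext <- purrr::map_dfr(1:8, function(s) {
    dec <- generate_decays(flat_pao2(15), peaks, 5, cal,
      seed = 500 + s,
      rep_rate = 700
    )
    tmin_tmax(phase_align(dec, peaks, calib = cal))
  })
  expect_true(all(ext$pao2_max > ext$pao2_min))
  expect_equal(
    wilcoxon_exact(ext$pao2_max - ext$pao2_min),
    2 / 2^8
  )
})
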