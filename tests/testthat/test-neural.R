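test_that("multitaper spectrogram concentrates tones and is flat on white noise", {
  sp <- multitaper_spectrogram(tone(60, 1000, 20), window = 1, step = 0.5)
  expect_equal(sp$freqs[which.max(colMeans(sp$power))], 60, tolerance = 5) # NW=5 half-bandwidth
  expect_true(all(sp$power >= 0))

  wn <- white_ts(30000, 1000, seed = 61)
  spw <- multitaper_spectrogram(wn, window = 1, step = 0.5)
  band <- spw$freqs >= 10 & spw$freqs <= 150
  lev <- colMeans(spw$power)[band]
  expect_lt(10 * log10(max(lev) / min(lev)), 3)

  z <- ts_new(rep(0, 5000), 1000)
  expect_equal(max(multitaper_spectrogram(z, 1, 0.5)$power), 0)
  expect_error(multitaper_spectrogram(tone(10, 100, 0.5), window = 1), "window longer")
})

test_that("gamma power integrates the right band and scales quadratically", {
  s60 <- multitaper_spectrogram(tone(60, 1000, 10), 1, 0.5)
  s150 <- multitaper_spectrogram(tone(150, 1000, 10), 1, 0.5)
  g60 <- mean(gamma_power(s60)$value)
  g150 <- mean(gamma_power(s150)$value)
  expect_gt(g60 / g150, 100)
  expect_equal(mean(gamma_power(s150, c(140, 160))$value), g60, tolerance = 0.05 * g60)

  # sign flip invariance and quadratic amplitude scaling
  x <- white_ts(10000, 1000, seed = 62)
  g1 <- gamma_power(multitaper_spectrogram(x, 1, 1))
  gneg <- gamma_power(multitaper_spectrogram(dplyr::mutate(x, value = -value), 1, 1))
  g2 <- gamma_power(multitaper_spectrogram(dplyr::mutate(x, value = 2 * value), 1, 1))
  expect_equal(g1$value, gneg$value, tolerance = 1e-12)
  expect_equal(g2$value, 4 * g1$value, tolerance = 1e-9)

  expect_error(gamma_power(multitaper_spectrogram(x, 1, 1), band = c(400, 600)), "outside")
})

test_that("generated sessions carry the configured gamma gain", {
  s <- quick_session(seed = 63, duration = 240, gamma_gain_loco = 2)
  sp <- multitaper_spectrogram(s$lfp, window = 1, step = 0.25)
  g <- gamma_power(sp)
  ind <- rep(0L, length(g$time))
  for (b in seq_len(nrow(s$truth$bouts))) {
    ind[g$time >= s$truth$bouts$onset[b] + 1 & g$time <= s$truth$bouts$offset[b] - 1] <- 1L
  }
  out <- g$time < min(s$truth$bouts$onset) - 2 |
    g$time > max(s$truth$bouts$offset) + 2
  expect_gte(sum(ind), 10) # this seed provides long bouts
  ratio <- mean(g$value[ind == 1]) / mean(g$value[out])
  expect_equal(ratio, 2, tolerance = 0.2)
})

test_that("evoked normalization divides by the pre-onset baseline", {
  # constant power -> identically 1
  p <- ts_new(rep(4, 600), rate = 10)
  ev <- tibble::tibble(onset = 20, offset = 30)
  en <- evoked_normalize(p, ev, baseline = 3)
  expect_true(all(abs(en$value - 1) < 1e-12))

  # x2 step at onset -> post-onset level 2
  v <- c(rep(1, 200), rep(2, 400))
  en2 <- evoked_normalize(ts_new(v, 10), ev, baseline = 3)
  expect_equal(unique(en2$value[en2$time > 0.5]), 2)

  # insufficient pre-data -> skipped with warning
  expect_warning(
    out <- evoked_normalize(p, tibble::tibble(onset = 0.1, offset = 5), baseline = 3),
    "skipped"
  )
  expect_equal(nrow(out), 0)
})

test_that("spike rate matches the analytic level-crossing rate and recovers injections", {
  # pure Gaussian white noise: upcrossing rate of a 3 sigma threshold
  withr::with_seed(64, {
    rate <- 20000
    x <- ts_new(stats::rnorm(10 * rate), rate)
    sr <- spike_rate(x, k_sd = 3, smooth = NULL)
    p_up <- stats::pnorm(3, lower.tail = FALSE) * stats::pnorm(3)
    expect_equal(mean(sr$value), p_up * rate, tolerance = 0.1 * p_up * rate)

    # injected 10 Hz spikes at 10 sigma with a high threshold
    n <- 20 * rate
    noise <- stats::rnorm(n)
    at <- sort(sample.int(n - 100, 200)) # 10 Hz over 20 s
    at <- at[c(TRUE, diff(at) > 60)]
    v <- noise
    tpl <- respox:::spike_template(0.5, rate)
    for (i in at) {
      idx <- i + seq_along(tpl$values) - 1
      v[idx] <- v[idx] + 10 * tpl$values
    }
    sr2 <- spike_rate(ts_new(v, rate), k_sd = 5, smooth = NULL)
    expect_equal(mean(sr2$value), length(at) / 20, tolerance = 1)

    # no spikes, 10 sigma threshold: essentially zero
    sr3 <- spike_rate(ts_new(noise, rate), k_sd = 10, smooth = NULL)
    expect_lt(mean(sr3$value), 0.05)
  })
  expect_error(spike_rate(ts_new(rep(1, 1000), 1000)), "zero-variance")
})

test_that("FS/RS classification separates the two templates by a single threshold", {
  s <- generate_session(
    session_config(duration_s = 120, mua_rate_rest = 10, spike_amp = 10),
    seed = 65, channels = "mua"
  )
  cl <- classify_fs_rs(bandpass(s$mua, 300, 3000))
  sp <- cl$spikes[cl$spikes$label != "unclassified", ]
  expect_gt(nrow(sp), 200)

  # accuracy against the generator's truth
  tr <- s$truth$spikes
  idx <- vapply(sp$time, function(t) which.min(abs(tr$time - t)), integer(1))
  match_ok <- abs(sp$time - tr$time[idx]) < 1e-3
  acc <- mean(sp$label[match_ok] == tr$kind[idx][match_ok])
  expect_gte(acc, 0.95)

  # labels are monotone in duration: one boundary separates them
  expect_lt(max(sp$ptt[sp$label == "FS"]), min(sp$ptt[sp$label == "RS"]))
  expect_true(is.finite(cl$mixture$boundary))
})

test_that("degenerate mixtures do not split a single template", {
  s <- generate_session(
    session_config(
      duration_s = 120, mua_rate_rest = 8, spike_amp = 10,
      fs_fraction = 1, ptt_jitter = 0.03
    ),
    seed = 66, channels = "mua"
  )
  cl <- classify_fs_rs(bandpass(s$mua, 300, 3000))
  lab <- unique(cl$spikes$label[cl$spikes$label != "unclassified"])
  expect_lte(length(lab), 1)
})

test_that("overlapping templates yield non-crossing label ranges", {
  s <- generate_session(
    session_config(
      duration_s = 180, mua_rate_rest = 10, spike_amp = 10,
      fs_ptt = 0.45, rs_ptt = 0.55, ptt_jitter = 0.1
    ),
    seed = 67, channels = "mua"
  )
  cl <- classify_fs_rs(bandpass(s$mua, 300, 3000))
  sp <- cl$spikes
  fs <- sp$ptt[sp$label == "FS"]
  rs <- sp$ptt[sp$label == "RS"]
  expect_gt(mean(sp$label == "unclassified"), 0.1)
  if (length(fs) > 0 && length(rs) > 0) {
    expect_lt(max(fs), min(rs))
  }
})

test_that("locomotion-evoked FS and RS rate changes agree on equal-gain data", {
  s <- generate_session(
    session_config(
      duration_s = 240, mua_rate_rest = 12, spike_amp = 10,
      mua_gain_loco = 2
    ),
    seed = 68, channels = "mua"
  )
  expect_gte(nrow(s$truth$bouts), 1)
  cl <- classify_fs_rs(bandpass(s$mua, 300, 3000))
  sp <- cl$spikes[cl$spikes$label != "unclassified", ]
  in_bout <- function(t) {
    any(t >= s$truth$bouts$onset & t <= s$truth$bouts$offset)
  }
  loco <- vapply(sp$time, in_bout, logical(1))
  t_loco <- sum(s$truth$bouts$offset - s$truth$bouts$onset)
  t_rest <- s$truth$config$duration_s - t_loco
  pct_change <- function(lab) {
    n_l <- sum(loco & sp$label == lab)
    n_r <- sum(!loco & sp$label == lab)
    r_l <- n_l / t_loco
    r_r <- n_r / t_rest
    se <- 100 * (r_l / r_r) * sqrt(1 / max(n_l, 1) + 1 / max(n_r, 1))
    c(change = 100 * (r_l - r_r) / r_r, se = se)
  }
  fs <- pct_change("FS")
  rs <- pct_change("RS")
  expect_lt(
    abs(fs["change"] - rs["change"]),
    2 * sqrt(fs["se"]^2 + rs["se"]^2)
  )
})
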