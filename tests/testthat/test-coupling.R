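test_that("cross-correlation normalization, identity and delay conventions hold", {
  x <- white_ts(4000, 30, seed = 31)
  xc <- xcorr(x, x, max_lag = 3, lp = NULL)
  pk <- attr(xc, "peak")
  expect_equal(pk$r_peak, 1, tolerance = 1e-12)
  expect_equal(pk$lag_peak, 0)
  expect_true(all(abs(xc$r) <= 1 + 1e-12))

  # y = x delayed by 2 s peaks at +2 s; brute-force shift-and-dot oracle
  withr::with_seed(32, {
    xv <- butter_zp(stats::rnorm(4000), 30, 3, 4, "low")
    lagn <- 60
    yv <- c(rep(0, lagn), xv[1:(4000 - lagn)])
    xs <- ts_new(xv, 30)
    ys <- ts_new(yv, 30)
    xc2 <- xcorr(xs, ys, max_lag = 4, lp = NULL)
    expect_equal(attr(xc2, "peak")$lag_peak, 2, tolerance = 1e-9)
    xm <- xv - mean(xv)
    ym <- yv - mean(yv)
    oracle <- vapply(seq(-120, 120), function(l) {
      if (l >= 0) {
        sum(xm[1:(4000 - l)] * ym[(1 + l):4000])
      } else {
        sum(xm[(1 - l):4000] * ym[1:(4000 + l)])
      }
    }, numeric(1)) / sqrt(sum(xm^2) * sum(ym^2))
    expect_equal(xc2$r, oracle, tolerance = 1e-12)
  })

  # independent white noise: all lags inside the 3/sqrt(n) null band
  a <- white_ts(10000, 100, seed = 33)
  b <- white_ts(10000, 100, seed = 34)
  xc3 <- xcorr(a, b, max_lag = 0.2, lp = NULL)
  expect_lt(max(abs(xc3$r)), 3 / sqrt(10000))

  expect_error(xcorr(ts_new(rep(1, 10000), 100), a, lp = NULL), "zero-variance")
})

test_that("xcorr recovers generator-imposed delays within one sample", {
  withr::with_seed(35, {
    rate <- 30
    base <- butter_zp(stats::rnorm(6000), rate, 0.5, 4, "low")
    for (delay_s in c(0.5, 2)) {
      n_l <- round(delay_s * rate)
      y <- ts_new(c(rep(0, n_l), base[1:(6000 - n_l)]) + stats::rnorm(6000, 0, 0.05), rate)
      x <- ts_new(base, rate)
      pk <- attr(xcorr(x, y, max_lag = 4), "peak")
      expect_equal(pk$lag_peak, delay_s, tolerance = 1 / rate + 1e-9)
    }
  })
})

test_that("surrogate band is calibrated and flags real coupling", {
  # ~5% of lags of independent signals fall outside the 95% band
  fr <- vapply(1:15, function(s) {
    a <- white_ts(5000, 30, seed = 200 + s)
    b <- white_ts(5000, 30, seed = 300 + s)
    sc <- surrogate_ci(a, b, max_lag = 3, n = 300, seed = s)
    mean(sc$r > sc$ci_hi | sc$r < sc$ci_lo)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.05), 0.02)

  # strongly coupled pair: the peak escapes the band
  withr::with_seed(36, {
    base <- butter_zp(stats::rnorm(5000), 30, 0.5, 4, "low")
    x <- ts_new(base + stats::rnorm(5000, 0, 0.02), 30)
    y <- ts_new(base + stats::rnorm(5000, 0, 0.02), 30)
    sc2 <- surrogate_ci(x, y, max_lag = 3, n = 300, seed = 1)
    at_peak <- which.max(abs(sc2$r))
    expect_gt(sc2$r[at_peak], sc2$ci_hi[at_peak])
  })

  # 100 vs 1000 surrogates agree within Monte-Carlo error
  a <- white_ts(4000, 30, seed = 44)
  b <- white_ts(4000, 30, seed = 45)
  s100 <- surrogate_ci(a, b, max_lag = 2, n = 100, seed = 2)
  s1000 <- surrogate_ci(a, b, max_lag = 2, n = 1000, seed = 2)
  expect_equal(mean(s100$ci_hi), mean(s1000$ci_hi), tolerance = 0.2 * mean(abs(s1000$ci_hi)))
})

test_that("coherence equals 1 for identical inputs and shows the estimator's null bias", {
  x <- white_ts(6000, 100, seed = 51)
  cxx <- coherence(x, x)
  expect_true(all(abs(cxx$c2 - 1) < 1e-9))
  expect_true(all(cxx$c2 >= 0 & cxx$c2 <= 1))

  y <- white_ts(6000, 100, seed = 52)
  cxy <- coherence(x, y)
  n_est <- attr(cxy, "n_est")
  expect_lt(abs(mean(cxy$c2) - 1 / n_est), 0.35 / n_est)

  # y = filtered x + noise: coherent in the pass band, not outside
  withr::with_seed(53, {
    xf <- butter_zp(x$value, 100, c(5, 15), 4, "pass")
    yb <- ts_new(xf + stats::rnorm(6000, 0, 0.08), 100)
    cb <- coherence(x, yb)
    inband <- cb$freq >= 7 & cb$freq <= 13
    outband <- cb$freq >= 30 & cb$freq <= 45
    expect_gt(mean(cb$c2[inband]), 0.8)
    expect_lt(mean(cb$c2[outband]), 0.2)
  })
  expect_error(coherence(x, y, nseg = 1), "identically 1")
})

test_that("partial coherence removes shared input and spares private coupling", {
  withr::with_seed(54, {
    n <- 8000
    z <- ts_new(stats::rnorm(n), 100)
    x <- ts_new(z$value + 0.4 * stats::rnorm(n), 100)
    y <- ts_new(z$value + 0.4 * stats::rnorm(n), 100)
    pc <- partial_coherence(x, y, z)
    expect_gt(mean(pc$c2), 0.5) # shared input gives high ordinary coherence
    expect_lt(mean(pc$pc2, na.rm = TRUE), 0.1) # removed by conditioning

    # conditioning on an independent channel leaves coherence untouched
    w <- ts_new(stats::rnorm(n), 100)
    xy_coupled <- ts_new(0.8 * x$value + 0.5 * stats::rnorm(n), 100)
    pc2 <- partial_coherence(x, xy_coupled, w)
    expect_equal(mean(pc2$pc2, na.rm = TRUE), mean(pc2$c2), tolerance = 0.05)

    # x = z exactly: total removal
    pc3 <- partial_coherence(x, y, x)
    expect_true(all(pc3$pc2[is.finite(pc3$pc2)] < 1e-6))

    # boundedness on random inputs
    for (s in 1:5) {
      a <- white_ts(3000, 50, seed = 600 + s)
      b <- white_ts(3000, 50, seed = 700 + s)
      cc <- white_ts(3000, 50, seed = 800 + s)
      pcr <- partial_coherence(a, b, cc)
      expect_true(all(pcr$c2 >= 0 & pcr$c2 <= 1))
      expect_true(all(pcr$pc2[is.finite(pcr$pc2)] >= 0))
    }
  })
})

test_that("band-resolved cross-correlogram confines coupling to the driving band", {
  withr::with_seed(55, {
    rate <- 400
    n <- 200 * rate / 10 # 200 s at 400 Hz is large; use 120 s
    n <- 120 * rate
    g <- butter_zp(stats::rnorm(n), rate, c(40, 60), 4, "pass")
    env <- butter_zp(abs(g), rate, 0.5, 4, "low")
    lfp <- ts_new(stats::rnorm(n, 0, 0.5) + g, rate)
    o2 <- ts_new(env + stats::rnorm(n, 0, 0.1 * stats::sd(env)), rate)
    bc <- band_crosscorrelogram(lfp, o2,
      band_lo = 10, band_hi = 90, band_step = 20,
      max_lag = 3, window = 1, step = 0.25
    )
    peak_by_band <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(bc), freq),
      peak = max(r), .groups = "drop"
    )
    drive <- peak_by_band$freq >= 40 & peak_by_band$freq <= 60
    expect_gt(min(peak_by_band$peak[drive]), max(peak_by_band$peak[!drive]))
  })
  expect_error(
    band_crosscorrelogram(
      white_ts(4000, 400, seed = 1),
      ts_new(rep(1, 4000), 400)
    ),
    "constant"
  )
})

test_that("exact signed-rank p-values match full enumeration and the printed cases", {
  # six all-positive pairs and nine all-positive pairs (two-sided)
  expect_equal(wilcoxon_exact(c(0.8, 1.2, 0.5, 2.1, 0.9, 1.7)), 2 / 2^6)
  expect_equal(round(wilcoxon_exact(rep(1, 6) + (1:6) / 100), 4), 0.0312)
  expect_equal(wilcoxon_exact((1:9) / 9), 2 / 2^9)
  expect_equal(signif(wilcoxon_exact((1:9) / 9), 2), 0.0039)

  # balanced symmetric signs: p = 1
  expect_equal(wilcoxon_exact(c(1, 2, 3, -1, -2, -3)), 1)

  # agreement with the brute-force 2^n enumeration for random patterns
  brute <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    rk <- rank(abs(d))
    w_obs <- sum(rk[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- signs %*% rk
    p_ge <- mean(w_all >= w_obs - 1e-9)
    p_le <- mean(w_all <= w_obs + 1e-9)
    min(1, 2 * min(p_ge, p_le))
  }
  withr::with_seed(77, {
    for (n in c(4, 7, 10, 12)) {
      d <- round(stats::rnorm(n), 2)
      d <- d[d != 0]
      expect_equal(wilcoxon_exact(d), brute(d), info = paste("n =", n))
    }
  })
  # and with R's exact test on tie-free data
  withr::with_seed(78, {
    d <- stats::rnorm(10)
    expect_equal(wilcoxon_exact(d), stats::wilcox.test(d, exact = TRUE)$p.value)
  })
  expect_error(wilcoxon_exact(rep(0, 5)), "zero")
})
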