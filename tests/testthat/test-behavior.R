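# brute-force interval scanners used as oracles for the event segmentation
scan_events <- function(delta, rate, min_pre, min_loco, merge_gap) {
  d <- delta$delta
  runs <- rle(d)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  on <- starts[runs$values == 1]
  off <- ends[runs$values == 1]
  # merge
  i <- 1
  while (i < length(on)) {
    if ((on[i + 1] - off[i] - 1) / rate < merge_gap) {
      off[i] <- off[i + 1]
      on <- on[-(i + 1)]
      off <- off[-(i + 1)]
    } else {
      i <- i + 1
    }
  }
  keep <- logical(length(on))
  for (i in seq_along(on)) {
    dur <- (off[i] - on[i] + 1) / rate
    pre_start <- on[i] - round(min_pre * rate)
    keep[i] <- dur >= min_loco && pre_start >= 1 &&
      all(d[pre_start:(on[i] - 1)] == 0) &&
      (i == 1 || off[i - 1] < pre_start)
  }
  cbind(on[keep], off[keep])
}

test_that("binarization follows the acceleration threshold rule", {
  # constant velocity -> zero acceleration -> all zeros
  v <- ts_new(rep(12, 5000), rate = 1000)
  expect_true(all(binarize_locomotion(v)$delta == 0))

  # triangular ramp with slope 5 cm/s^2 -> detected for the whole ramp
  rate <- 1000
  ramp <- c(rep(0, 3000), seq(0, 5, length.out = 1000), rep(5, 3000))
  d <- binarize_locomotion(ts_new(ramp, rate))
  core <- 3200:3800 # inside the ramp, away from filter transients
  expect_true(all(d$delta[core] == 1))
  expect_true(all(d$delta[1:2500] == 0))

  # threshold is inclusive: |a| exactly at a_c marks the sample
  a_c <- 3
  acc <- rep(0, 4000)
  acc[2001:2600] <- a_c # plateau exactly at threshold
  vel <- cumsum(acc) / rate
  d2 <- binarize_locomotion(ts_new(vel, rate), a_c = a_c)
  expect_true(any(d2$delta[2050:2550] == 1))
})

test_that("binarization is scale-consistent", {
  s <- quick_session(seed = 21)
  d1 <- binarize_locomotion(s$velocity, a_c = 3)
  v2 <- dplyr::mutate(s$velocity, value = 2 * value)
  d2 <- binarize_locomotion(v2, a_c = 6)
  expect_equal(d1$delta, d2$delta)
})

test_that("evoked-event segmentation applies the pre-rest and duration rules", {
  rate <- 100
  mk <- function(spans, total = 60) {
    d <- integer(total * rate)
    for (sp in spans) d[(sp[1] * rate + 1):(sp[2] * rate)] <- 1L
    tibble::tibble(time = (seq_along(d) - 1) / rate, delta = d)
  }
  # 6 s run preceded by 4 s quiescence -> one evoked event
  ev <- segment_events(mk(list(c(10, 16))), min_pre_rest = 3, min_loco = 5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, 10, tolerance = 0.02)
  # 6 s run preceded by only 2 s quiescence -> rejected
  ev2 <- segment_events(mk(list(c(2, 8))), min_pre_rest = 3, min_loco = 5)
  expect_equal(nrow(ev2), 0)
  # two runs: the second fails the 3 s pre-rest rule (2 s gap)
  ev3 <- segment_events(mk(list(c(10, 16), c(18, 25))),
    min_pre_rest = 3, min_loco = 5, merge_gap = 0.5
  )
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$onset, 10, tolerance = 0.02)
})

test_that("segmentation and rest periods agree with a brute-force scan on random bouts", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      rate <- 50
      d <- integer(60 * rate)
      n_b <- sample(3:8, 1)
      pos <- sort(sample(seq(2, 55), n_b))
      for (p in pos) d[(p * rate):((p + stats::runif(1, 0.5, 6)) * rate)] <- 1L
      delta <- tibble::tibble(time = (seq_along(d) - 1) / rate, delta = d)
      ev <- segment_events(delta, min_pre_rest = 3, min_loco = 5, merge_gap = 0.5)
      oracle <- scan_events(delta, rate, 3, 5, 0.5)
      expect_equal(nrow(ev), nrow(oracle))
      if (nrow(ev) > 0) {
        expect_equal(ev$onset, delta$time[oracle[, 1]], tolerance = 1e-9)
      }
      # rest intervals never overlap locomotion, and pre-windows are silent
      rests <- rest_periods(delta, post_gap = 4, min_dur = 10)
      for (i in seq_len(nrow(rests))) {
        sel <- delta$time >= rests$onset[i] & delta$time < rests$offset[i]
        expect_true(all(delta$delta[sel] == 0))
      }
      for (i in seq_len(nrow(ev))) {
        sel <- delta$time >= ev$onset[i] - 3 & delta$time < ev$onset[i]
        expect_true(all(delta$delta[sel] == 0))
      }
    }
  })
})

test_that("rest periods honour the post-bout buffer and minimum duration", {
  rate <- 100
  d <- integer(60 * rate)
  d[(10 * rate + 1):(15 * rate)] <- 1L
  d[(22 * rate + 1):(40 * rate)] <- 1L
  delta <- tibble::tibble(time = (seq_along(d) - 1) / rate, delta = d)
  rests <- rest_periods(delta, post_gap = 4, min_dur = 10)
  # candidates: (0,10) len 10 (not > 10), (19,22) len 3, (44,60) len 16
  expect_equal(nrow(rests), 1)
  expect_equal(rests$onset, 44, tolerance = 0.02)
  expect_equal(rests$offset, 60, tolerance = 0.02)

  all_zero <- tibble::tibble(time = (0:5999) / 100, delta = 0L)
  r0 <- rest_periods(all_zero)
  expect_equal(nrow(r0), 1)
  expect_equal(r0$duration, 60, tolerance = 0.02)
})
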