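# Shared fixtures built in code. Everything is seeded and small enough to
# keep the default test run fast.

tone <- function(freq, rate, dur, amp = 1, phase = 0) {
  ts_new(amp * sin(2 * pi * freq * (0:(round(dur * rate) - 1)) / rate + phase),
    rate = rate
  )
}

white_ts <- function(n, rate, sd = 1, seed = 1) {
  withr::with_seed(seed, ts_new(stats::rnorm(n, 0, sd), rate = rate))
}

# small, quiet session used by several modules
quick_session <- function(seed = 1, duration = 60, ...) {
  generate_session(session_config(duration_s = duration, ...), seed = seed)
}

regular_peaks <- function(dur = 20, freq = 2.5, t0 = 0.2) {
  seq(t0, dur, by = 1 / freq)
}

flat_pao2 <- function(dur = 20, po2 = 35, rate = 100) {
  ts_new(rep(po2, round(dur * rate)), rate = rate)
}
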