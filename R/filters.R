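# Internal zero-phase filtering machinery.
#
# All user-facing filters are applied forward-backward (zero-phase), so
# filtered features keep their timing relative to behavioral events.
# Butterworth filters are implemented as cascaded second-order sections
# (biquads): single transfer-function polynomials of order >= 5 are
# numerically unstable at the very low normalized cutoffs this pipeline
# needs (e.g. a 1 Hz low-pass on a 1 kHz channel), while biquad cascades are
# accurate there. Band-passes cascade a high-pass and a low-pass. The
# digital Bessel design (used for spike-rate smoothing) is built from the
# analog Bessel polynomial prototype via a prewarped bilinear transform.

# Analog Butterworth prototype poles (unit cutoff), left half plane.
butter_proto_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# Second-order sections for a digital Butterworth filter.
# Each section: list(b = c(b0, b1, b2), a = c(1, a1, a2)).
butter_sos <- function(order, cutoff, rate, type = c("low", "high")) {
  type <- match.arg(type)
  if (cutoff <= 0 || cutoff >= rate / 2) {
    stop("filter cutoff must lie strictly inside (0, Nyquist)", call. = FALSE)
  }
  fs2 <- 2 * rate
  wa <- fs2 * tan(pi * cutoff / rate)
  proto <- butter_proto_poles(order)
  pa <- if (type == "low") wa * proto else wa / proto
  pz <- (fs2 + pa) / (fs2 - pa)
  zero <- if (type == "low") -1 else 1
  eval_at <- if (type == "low") 1 else -1 # normalize at DC / Nyquist
  # pair complex-conjugate poles; n odd leaves one real pole
  ord <- order(abs(Im(pz)), Re(pz))
  pz <- pz[ord]
  used <- rep(FALSE, order)
  sections <- list()
  for (i in seq_len(order)) {
    if (used[i]) next
    p <- pz[i]
    used[i] <- TRUE
    if (abs(Im(p)) > 1e-12) {
      j <- which(!used & abs(pz - Conj(p)) < 1e-8)[1]
      used[j] <- TRUE
      a <- c(1, -2 * Re(p), Mod(p)^2)
      b <- c(1, -2 * zero, 1)
    } else {
      a <- c(1, -Re(p), 0)
      b <- c(1, -zero, 0)
    }
    # gain at z = eval_at: sum(coef * z^(0,-1,-2))
    zp <- eval_at^c(0, -1, -2)
    g <- sum(b * zp) / sum(a * zp)
    sections[[length(sections) + 1L]] <- list(b = b / g, a = a)
  }
  sections
}

# Forward-backward filtering of a cascade of sections. Edge transients are
# suppressed by reflective padding plus exact handling of the DC offset:
# the boundary value is subtracted before each pass and re-added scaled by
# the section's DC gain, so a constant input passes through untouched.
sos_zp <- function(x, sections) {
  n <- length(x)
  np <- min(n - 1L, 6000L)
  pre <- 2 * x[1] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- c(pre, x, post)
  one_pass <- function(v, s) {
    g_dc <- sum(s$b) / sum(s$a)
    m <- v[1]
    signal::filter(signal::Arma(b = s$b, a = s$a), v - m) + m * g_dc
  }
  for (s in sections) {
    y <- one_pass(y, s)
    y <- rev(one_pass(rev(y), s))
  }
  y[(np + 1L):(np + n)]
}

butter_zp <- function(x, rate, cutoff, order = 5, type = "low") {
  sections <- switch(type,
    low = butter_sos(order, cutoff, rate, "low"),
    high = butter_sos(order, cutoff, rate, "high"),
    pass = c(
      butter_sos(order, cutoff[1], rate, "high"),
      butter_sos(order, cutoff[2], rate, "low")
    ),
    stop("unknown filter type", call. = FALSE)
  )
  sos_zp(x, sections)
}

# Reverse Bessel polynomial coefficients theta_n(s), descending powers.
bessel_poly <- function(n) {
  k <- 0:n
  coef <- factorial(2 * n - k) / (2^(n - k) * factorial(k) * factorial(n - k))
  rev(coef) # c(s^n, ..., s^0)
}

# Digital low-pass Bessel filter (b, a), -3 dB point at `cutoff` Hz.
bessel_design <- function(order, cutoff, rate) {
  if (cutoff <= 0 || cutoff >= rate / 2) {
    stop("filter cutoff must lie strictly inside (0, Nyquist)", call. = FALSE)
  }
  p <- polyroot(bessel_poly(order)) # analog prototype poles
  # normalize prototype so |H(j w)| = 1/sqrt(2) at w = 1
  gain0 <- abs(prod(-p))
  mag2 <- function(w) {
    abs(gain0 / prod(1i * w - p))^2 - 0.5
  }
  w3 <- stats::uniroot(Vectorize(mag2), c(1e-3, 10), tol = 1e-12)$root
  fs2 <- 2 * rate
  wa <- fs2 * tan(pi * cutoff / rate) # prewarped analog cutoff (rad/s)
  pa <- p * (wa / w3)
  # bilinear transform: poles -> z-plane, `order` zeros at z = -1
  pz <- (fs2 + pa) / (fs2 - pa)
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * (sum(a) / sum(b)) # unit DC gain
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
  coef
}

bessel_zp <- function(x, rate, cutoff, order = 4) {
  flt <- bessel_design(order, cutoff, rate)
  n <- length(x)
  np <- min(n - 1L, 3000L)
  pre <- 2 * x[1] - x[pmin(np + 1L, n):2L]
  post <- 2 * x[n] - x[(n - 1L):max(n - np, 1L)]
  y <- c(pre, x, post)
  y <- signal::filter(signal::Arma(b = flt$b, a = flt$a), y)
  y <- rev(signal::filter(signal::Arma(b = flt$b, a = flt$a), rev(y)))
  y[(length(pre) + 1L):(length(pre) + n)]
}
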