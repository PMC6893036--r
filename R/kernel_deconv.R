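#' Lagged design matrix for response-function deconvolution
#'
#' Builds the Toeplitz-structured design used to estimate hemodynamic and
#' neural response functions: an intercept column of ones followed by `k`
#' progressively delayed copies of the binarized locomotion regressor
#' (zero-filled at the record start, no wraparound). Column `j + 1` carries
#' the regressor delayed by `j - 1` samples.
#'
#' @param delta Binarized locomotion tibble (columns `time`, `delta`).
#' @param k Number of kernel lags (>= 1, < record length).
#' @return Numeric matrix of dimension `n x (k + 1)` with attributes `rate`
#'   and `lags` (seconds).
#' @export
build_design <- function(delta, k) {
  d <- as.numeric(delta[["delta"]])
  n <- length(d)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k >= n) stop("k must be smaller than the record length", call. = FALSE)
  rate <- ts_rate(delta)
  L <- matrix(0, n, k + 1L)
  L[, 1L] <- 1
  for (j in seq_len(k)) {
    L[j:n, j + 1L] <- d[1:(n - j + 1L)]
  }
  attr(L, "rate") <- rate
  attr(L, "lags") <- (seq_len(k) - 1L) / rate
  L
}

#' Estimate a response function by least-squares deconvolution
#'
#' Solves `V ~ L %*% H` for the impulse response `H` mapping binarized
#' locomotion to the observed signal (tissue oxygen, gamma-band power, ...).
#' The least-squares problem is solved by QR factorization (or an SVD
#' pseudoinverse), never by explicitly forming the normal equations, which is
#' numerically safer and algebraically identical. An optional ridge penalty
#' is available for ill-conditioned real recordings but is off by default.
#'
#' @param v Time-series tibble of the signal, sampled at the design's rate.
#' @param design Design matrix from [build_design()].
#' @param method `"qr"` (default) or `"pinv"`.
#' @param ridge Non-negative ridge penalty on the kernel coefficients.
#' @return An object of class `ox_kernel` with the lag-indexed kernel, the
#'   intercept, the residual norm, and peak/onset summary metrics.
#' @export
#' @examples
#' d <- ts_new(rep(c(0, 1, 0, 0), each = 75), rate = 30)
#' names(d)[2] <- "delta"
#' L <- build_design(d, k = 60)
#' h_true <- exp(-(0:59) / 15) * sin((0:59) / 8)
#' v <- tibble::tibble(time = d$time, value = drop(L %*% c(1, h_true)))
#' fit <- deconvolve(v, L)
deconvolve <- function(v, design, method = c("qr", "pinv"), ridge = 0) {
  method <- match.arg(method)
  y <- ts_values(v)
  if (length(y) != nrow(design)) {
    stop("signal length must match the design matrix rows; resample to a common rate first",
      call. = FALSE
    )
  }
  k <- ncol(design) - 1L
  X <- design
  if (ridge > 0) {
    X <- rbind(design, cbind(0, diag(sqrt(ridge), k)))
    y <- c(y, numeric(k))
  }
  if (method == "qr") {
    fit <- stats::.lm.fit(X, y)
    if (fit$rank < ncol(X)) {
      stop("design matrix is rank deficient: not enough locomotion events to constrain the kernel",
        call. = FALSE
      )
    }
    coefs <- fit$coefficients[order(fit$pivot)]
  } else {
    sv <- svd(X)
    tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
    pos <- sv$d > tol
    if (sum(pos) < ncol(X)) {
      stop("design matrix is rank deficient: not enough locomotion events to constrain the kernel",
        call. = FALSE
      )
    }
    coefs <- sv$v %*% ((crossprod(sv$u, y))[, 1] / sv$d)
    coefs <- drop(coefs)
  }
  resid <- drop(design %*% coefs) - ts_values(v)
  kern <- tibble::tibble(lag = attr(design, "lags"), value = coefs[-1L])
  out <- structure(
    list(
      kernel = kern,
      intercept = coefs[1L],
      residual_norm = sqrt(sum(resid^2)),
      rate = attr(design, "rate"),
      method = method
    ),
    class = "ox_kernel"
  )
  out$metrics <- kernel_metrics(out)
  out
}

#' Summary metrics of a response-function kernel
#'
#' The peak amplitude is the signed extremal value of the kernel (dominant
#' lobe), the peak time its lag, and the onset time the first lag at which
#' the kernel reaches 10% of the peak amplitude in the peak's direction. The
#' onset threshold is a reporting convention, exposed via `onset_frac`.
#'
#' @param kernel An `ox_kernel` object or a tibble with `lag` and `value`.
#' @param onset_frac Fraction of peak amplitude defining onset.
#' @return One-row tibble with `peak_amplitude`, `peak_time`, `onset_time`.
#' @export
kernel_metrics <- function(kernel, onset_frac = 0.1) {
  kt <- if (inherits(kernel, "ox_kernel")) kernel$kernel else kernel
  val <- kt[["value"]]
  lag <- kt[["lag"]]
  if (length(val) == 0L) stop("kernel is empty", call. = FALSE)
  if (all(val == 0)) {
    warning("all-zero kernel: metrics undefined")
    return(tibble::tibble(
      peak_amplitude = NA_real_, peak_time = NA_real_,
      onset_time = NA_real_
    ))
  }
  ipk <- which.max(abs(val))
  pk <- val[ipk]
  thr <- onset_frac * abs(pk)
  on_idx <- which(sign(pk) * val >= thr)[1L]
  tibble::tibble(
    peak_amplitude = pk,
    peak_time = lag[ipk],
    onset_time = lag[on_idx]
  )
}

#' @export
tidy.ox_kernel <- function(x, ...) x$kernel

#' @export
glance.ox_kernel <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      intercept = x$intercept,
      residual_norm = x$residual_norm,
      n_lags = nrow(x$kernel),
      rate = x$rate
    ),
    x$metrics
  )
}

#' @export
print.ox_kernel <- function(x, ...) {
  cat(sprintf(
    "<ox_kernel> %d lags @ %.6g Hz | intercept %.4g | peak %.4g at %.3g s (onset %.3g s)\n",
    nrow(x$kernel), x$rate, x$intercept,
    x$metrics$peak_amplitude, x$metrics$peak_time, x$metrics$onset_time
  ))
  invisible(x)
}

#' Predicted response from a fitted kernel
#'
#' Convolves a fitted response function with a binarized locomotion trace,
#' giving the modelled "net" signal (intercept included), e.g. to compare a
#' predicted oxygen response against the measured one.
#'
#' @param object Fitted `ox_kernel`.
#' @param delta Binarized locomotion tibble at the kernel's rate.
#' @param ... Unused.
#' @return Time-series tibble of the predicted signal.
#' @export
predict.ox_kernel <- function(object, delta, ...) {
  L <- build_design(delta, nrow(object$kernel))
  tibble::tibble(
    time = delta[["time"]],
    value = drop(L %*% c(object$intercept, object$kernel$value))
  )
}

#' @export
autoplot.ox_kernel <- function(object, ...) {
  ggplot2::ggplot(object$kernel, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = object$metrics$peak_time,
      linetype = 3, colour = "firebrick"
    ) +
    ggplot2::labs(x = "lag (s)", y = "response per unit locomotion") +
    ggplot2::theme_minimal()
}
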