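#' Savitzky-Golay configuration
#'
#' Parameters of the Savitzky-Golay smoothing filter: the filter replaces each
#' sample by the centre value of the least-squares polynomial of degree `N`
#' fitted over the window of `2M + 1` samples around it. The defaults
#' `N = 3, M = 11` are the values found to work best for stethoscope lung
#' sounds.
#'
#' @param M half-window size in samples; the window width is `2M + 1`.
#' @param N polynomial degree; must satisfy `N < 2M + 1` or the per-window
#'   least-squares problem is underdetermined.
#' @return An object of class `sg_config`.
#' @export
sg_config <- function(M = 11L, N = 3L) {
  M <- as.integer(M); N <- as.integer(N)
  if (M < 1L) stop("M must be >= 1")
  if (N < 0L) stop("N must be >= 0")
  if (N >= 2L * M + 1L) {
    stop(sprintf("polynomial degree N = %d must be < window width 2M+1 = %d",
                 N, 2L * M + 1L))
  }
  structure(list(M = M, N = N), class = "sg_config")
}

# Centre row of the least-squares projection matrix for abscissae -M..M and
# degree N: convolving with it reproduces any degree-<=N polynomial exactly.
sg_center_coefficients <- function(M, N) {
  x <- seq.int(-M, M)
  A <- outer(x, 0:N, `^`)
  # h = e1' (A'A)^{-1} A'  evaluated at 0: only the intercept row matters
  h <- solve(crossprod(A), t(A))[1L, ]
  unname(h)
}

# Least-squares polynomial fit on arbitrary abscissae, evaluated at x0.
sg_fit_eval <- function(y, x, N, x0) {
  A <- outer(x - x0, 0:N, `^`)
  beta <- qr.solve(A, y)
  beta[1L]
}

#' Savitzky-Golay smoothing of a signal
#'
#' Smooths a signal by local least-squares polynomial fitting: each output
#' sample is the centre value of the degree-`N` polynomial fitted over the
#' surrounding `2M + 1` samples. Polynomials of degree at most `N` pass
#' through the filter unchanged, so genuine low-order structure is preserved
#' while high-frequency noise is attenuated. At the first and last `M`
#' samples, where the symmetric window does not fit, the polynomial is fitted
#' on the truncated one-sided window and evaluated at the sample position, so
#' the output has the same length as the input.
#'
#' @param x a [sm_signal] or numeric vector.
#' @param cfg an [sg_config]; defaults to `N = 3, M = 11`.
#' @param rate sample rate, only needed when `x` is a bare numeric vector.
#' @return A smoothed object of the same type as `x`.
#' @examples
#' t <- seq(0, 1, length.out = 200)
#' noisy <- sm_signal(sin(2 * pi * 3 * t) + rnorm(200, sd = 0.1), rate = 200)
#' smooth <- savitzky_golay(noisy)
#' @export
savitzky_golay <- function(x, cfg = sg_config(), rate = NULL) {
  stopifnot(inherits(cfg, "sg_config"))
  sig <- if (inherits(x, "sm_signal")) x else as_sm_signal(x, rate)
  y <- sig$samples
  n <- length(y)
  M <- cfg$M; N <- cfg$N
  w <- 2L * M + 1L
  if (n < w) {
    stop(sprintf("signal has %d samples but the window needs 2M+1 = %d", n, w))
  }

  h <- sg_center_coefficients(M, N)
  # interior: plain convolution with the centre projection row
  out <- stats::filter(y, rev(h), sides = 2L)
  out <- as.numeric(out)

  # edges: truncated one-sided windows, degree reduced if the window is short
  for (i in seq_len(M)) {
    idx <- 1:(i + M)
    deg <- min(N, length(idx) - 1L)
    out[i] <- sg_fit_eval(y[idx], as.numeric(idx), deg, as.numeric(i))
    j <- n - i + 1L
    idx <- (j - M):n
    deg <- min(N, length(idx) - 1L)
    out[j] <- sg_fit_eval(y[idx], as.numeric(idx), deg, as.numeric(j))
  }

  if (inherits(x, "sm_signal")) {
    sm_signal(out, sig$rate, id = sig$id, group = sig$group)
  } else {
    out
  }
}
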