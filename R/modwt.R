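#' @name modwt
#' @title Maximal-overlap discrete wavelet transform (MODWT)
#'
#' @description
#' Undecimated (shift-invariant) wavelet decomposition by the pyramid
#' algorithm with circular boundary handling. Unlike the decimated DWT, the
#' MODWT keeps every coefficient at every level, so the transform of an
#' arbitrary-length signal is well defined and exactly invertible.
#'
#' `modwt()` returns the detail coefficient vectors `W1..WJ` and the final
#' smooth `VJ`; `imodwt()` reconstructs the signal from them.
#'
#' @param x numeric vector.
#' @param wavelet filter name, one of `"haar"`, `"d4"`.
#' @param levels number of decomposition levels `J >= 1`.
#' @param w a list as returned by `modwt()`.
#' @return `modwt()`: a list with components `W` (list of J detail vectors),
#'   `V` (smooth at level J), `wavelet`, `levels`, `n`. `imodwt()`: the
#'   reconstructed numeric vector.
NULL

modwt_filters <- function(wavelet) {
  g <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    stop(sprintf("unknown wavelet '%s' (available: haar, d4)", wavelet))
  )
  L <- length(g)
  # quadrature mirror: h_l = (-1)^l g_{L-1-l}
  h <- rev(g) * (-1)^(seq_len(L) - 1L)
  # MODWT rescaling
  list(g = g / sqrt(2), h = h / sqrt(2), L = L)
}

# y[t] = sum_l f[l+1] * x[(t - s*l) mod n]   (analysis step, circular)
modwt_conv_down <- function(x, f, s) {
  n <- length(x)
  y <- numeric(n)
  t <- seq_len(n)
  for (l in seq_along(f) - 1L) {
    idx <- ((t - 1L - s * l) %% n) + 1L
    y <- y + f[l + 1L] * x[idx]
  }
  y
}

# y[t] = sum_l f[l+1] * x[(t + s*l) mod n]   (synthesis step, circular)
modwt_conv_up <- function(x, f, s) {
  n <- length(x)
  y <- numeric(n)
  t <- seq_len(n)
  for (l in seq_along(f) - 1L) {
    idx <- ((t - 1L + s * l) %% n) + 1L
    y <- y + f[l + 1L] * x[idx]
  }
  y
}

#' @rdname modwt
#' @export
modwt <- function(x, wavelet = "d4", levels = 4L) {
  x <- as.numeric(x)
  n <- length(x)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  if (2^levels > n) {
    stop(sprintf("levels = %d infeasible for signal of length %d", levels, n))
  }
  flt <- modwt_filters(wavelet)
  W <- vector("list", levels)
  V <- x
  for (j in seq_len(levels)) {
    s <- 2L^(j - 1L)
    W[[j]] <- modwt_conv_down(V, flt$h, s)
    V <- modwt_conv_down(V, flt$g, s)
  }
  list(W = W, V = V, wavelet = wavelet, levels = levels, n = n)
}

#' @rdname modwt
#' @export
imodwt <- function(w) {
  flt <- modwt_filters(w$wavelet)
  V <- w$V
  for (j in rev(seq_len(w$levels))) {
    s <- 2L^(j - 1L)
    V <- modwt_conv_up(w$W[[j]], flt$h, s) + modwt_conv_up(V, flt$g, s)
  }
  V
}

#' Wavelet denoising by MODWT coefficient thresholding
#'
#' Decomposes the signal with the maximal-overlap discrete wavelet transform,
#' shrinks the detail coefficients, and inverts the transform. The default
#' rule applies the universal threshold `lambda = sigma * sqrt(2 log n)` with
#' soft thresholding at every level, where `sigma` is the robust (MAD-based)
#' noise scale estimated from the level-1 detail coefficients. Because the
#' MODWT is exactly invertible, a zero threshold returns the input unchanged
#' (up to round-off).
#'
#' @param x a [sm_signal] or numeric vector.
#' @param wavelet filter name passed to [modwt()]; default `"d4"`.
#' @param levels decomposition depth; default 4.
#' @param threshold_rule `"universal_soft"` (default) or `"universal_hard"`.
#' @param threshold optional fixed threshold overriding the universal rule
#'   (0 disables shrinkage entirely).
#' @param rate sample rate, only needed when `x` is a bare numeric vector.
#' @return A denoised object of the same type as `x`.
#' @export
modwt_denoise <- function(x, wavelet = "d4", levels = 4L,
                          threshold_rule = c("universal_soft",
                                             "universal_hard"),
                          threshold = NULL, rate = NULL) {
  threshold_rule <- match.arg(threshold_rule)
  sig <- if (inherits(x, "sm_signal")) x else as_sm_signal(x, rate)
  y <- sig$samples
  w <- modwt(y, wavelet = wavelet, levels = levels)

  if (is.null(threshold)) {
    sigma <- stats::mad(w$W[[1L]], center = 0)
    lambda <- sigma * sqrt(2 * log(length(y)))
  } else {
    lambda <- threshold
  }

  shrink <- if (threshold_rule == "universal_soft") {
    function(d) sign(d) * pmax(abs(d) - lambda, 0)
  } else {
    function(d) d * (abs(d) > lambda)
  }
  w$W <- lapply(w$W, shrink)
  out <- imodwt(w)

  if (inherits(x, "sm_signal")) {
    sm_signal(out, sig$rate, id = sig$id, group = sig$group)
  } else {
    out
  }
}
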