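#' Construct a spectrogram surface
#'
#' A `sm_surface` is the discretized graph `{(x, y, z(x, y))}` of a
#' time-frequency magnitude representation on a uniform `N x N` grid: `times`
#' along x, `freqs` along y, and `z[i, j]` the normalized log-magnitude at
#' `(times[i], freqs[j])`. After normalization all three coordinates lie in
#' `[0, 1]`, with `z` further multiplied by the aspect factor `alpha`; the
#' original spans and the magnitude transform are kept in `scale_meta` so the
#' geometry of downstream features is reproducible.
#'
#' @param times,freqs strictly increasing, uniformly spaced coordinate
#'   vectors of equal length.
#' @param z numeric matrix, `length(times)` rows x `length(freqs)` columns.
#' @param scale_meta list of provenance fields (original spans, magnitude
#'   transform, aspect `alpha`).
#' @return An object of class `sm_surface`.
#' @export
sm_surface <- function(times, freqs, z, scale_meta = list()) {
  times <- as.numeric(times); freqs <- as.numeric(freqs)
  z <- as.matrix(z)
  if (nrow(z) != length(times) || ncol(z) != length(freqs)) {
    stop("z must be length(times) x length(freqs)")
  }
  if (!all(is.finite(z))) stop("z must be finite")
  check_uniform <- function(v, what) {
    if (length(v) < 2L) stop(sprintf("%s needs at least 2 points", what))
    d <- diff(v)
    if (any(d <= 0)) stop(sprintf("%s must be strictly increasing", what))
    if (max(d) - min(d) > 1e-8 * max(abs(d))) {
      stop(sprintf("%s must be uniformly spaced", what))
    }
  }
  check_uniform(times, "times")
  check_uniform(freqs, "freqs")
  structure(list(times = times, freqs = freqs, z = z,
                 scale_meta = scale_meta),
            class = "sm_surface")
}

#' @export
print.sm_surface <- function(x, ...) {
  cat(sprintf("<sm_surface %d x %d, z in [%.3g, %.3g]>\n",
              length(x$times), length(x$freqs), min(x$z), max(x$z)))
  invisible(x)
}

# map a vector affinely onto [0, 1]; constant vectors collapse to 0
unit_rescale <- function(v) {
  r <- range(v)
  if (r[2] - r[1] <= 0) return(list(v = rep(0, length(v)), span = r))
  list(v = (v - r[1]) / (r[2] - r[1]), span = r)
}

#' Normalize a spectrogram surface to the unit box
#'
#' Affinely maps times, freqs and z each onto `[0, 1]`, then multiplies z by
#' the aspect factor `alpha`. Normalizing an already-normalized surface (same
#' `alpha`) is the identity. A constant-z surface maps to `z == 0`.
#'
#' @param s a [sm_surface].
#' @param alpha z aspect factor (height of the surface box relative to its
#'   unit footprint); default 1.
#' @return A normalized [sm_surface]; original spans recorded in
#'   `scale_meta`.
#' @export
normalize_surface <- function(s, alpha = 1) {
  stopifnot(inherits(s, "sm_surface"))
  tt <- unit_rescale(s$times)
  ff <- unit_rescale(s$freqs)
  zr <- range(s$z)
  z <- if (zr[2] - zr[1] > 0) (s$z - zr[1]) / (zr[2] - zr[1]) else s$z * 0
  meta <- s$scale_meta
  # keep the outermost (pre-normalization) spans if already recorded
  if (is.null(meta$time_span)) meta$time_span <- tt$span
  if (is.null(meta$freq_span)) meta$freq_span <- ff$span
  if (is.null(meta$z_range)) meta$z_range <- zr
  meta$alpha <- alpha
  sm_surface(tt$v, ff$v, z * alpha, meta)
}

# Resampling of z (rows ~ src_x, cols ~ src_y) onto dst grids. When the
# destination is coarser than the source the axis is box-averaged
# (anti-aliased): each destination sample is the mean of the source samples
# in its cell. Point interpolation of a coarse grid onto a narrow spectral
# ridge would make the surface hypersensitive to ridge/grid alignment.
# When the destination is finer, linear interpolation is used.
resample_grid <- function(z, src_x, src_y, dst_x, dst_y) {
  along <- function(M, src, dst) {   # resample rows of M indexed by src
    src_sp <- if (length(src) > 1) (max(src) - min(src)) / (length(src) - 1) else Inf
    dst_sp <- if (length(dst) > 1) (dst[2] - dst[1]) else Inf
    if (dst_sp > src_sp) {
      hw <- dst_sp / 2
      out <- matrix(0, length(dst), ncol(M))
      for (i in seq_along(dst)) {
        sel <- which(src >= dst[i] - hw & src <= dst[i] + hw)
        if (!length(sel)) sel <- which.min(abs(src - dst[i]))
        out[i, ] <- colMeans(M[sel, , drop = FALSE])
      }
      out
    } else {
      apply(M, 2L, function(col) {
        stats::approx(src, col, xout = dst, rule = 2)$y
      })
    }
  }
  zt <- along(z, src_x, dst_x)
  t(along(t(zt), src_y, dst_y))
}

# triangular mel filterbank on the FFT bin frequencies (HTK mel scale)
mel_filterbank <- function(freqs_hz, n_mels, fmin = 0, fmax = max(freqs_hz)) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  mpts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L)
  fpts <- mel_to_hz(mpts)
  fb <- matrix(0, n_mels, length(freqs_hz))
  for (m in seq_len(n_mels)) {
    lo <- fpts[m]; ce <- fpts[m + 1L]; hi <- fpts[m + 2L]
    up <- (freqs_hz - lo) / (ce - lo)
    dn <- (hi - freqs_hz) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  list(fb = fb, centers = fpts[2:(n_mels + 1L)])
}

# magnitude STFT via signal::specgram; returns |S| (freq x time), f, t
stft_magnitude <- function(samples, rate, window, overlap) {
  sp <- signal::specgram(samples, n = window, Fs = rate,
                         window = signal::hanning(window),
                         overlap = floor(overlap * window))
  list(mag = abs(sp$S), f = as.numeric(sp$f), t = as.numeric(sp$t))
}

#' Compute the spectrogram surface of a signal
#'
#' Computes a magnitude spectrogram (plain STFT, or mel-filterbank
#' spectrogram for speech-type signals), converts it to log scale, resamples
#' it bilinearly onto a uniform `grid_N x grid_N` time-frequency grid, and
#' normalizes the axes to the unit box (see [normalize_surface()]). The
#' result is the surface that is subsequently triangulated and flattened.
#'
#' The analysis window defaults to the power of two giving roughly four
#' frequency bins per target grid row (so the box-averaged downsampling has
#' material to average), shrunk as needed so at least `grid_N` frames fit
#' at the given overlap (bounded to `[8, 1024]`); window length, overlap
#' and the number of mel bands can be pinned through `stft_params`.
#'
#' @param x a [sm_signal] or numeric vector.
#' @param kind `"stft"` or `"mel"`.
#' @param stft_params optional list with elements `window` (samples),
#'   `overlap` (fraction, default 0.75), `n_mels` (default 64).
#' @param grid_N grid resolution per axis; default 64.
#' @param alpha z aspect factor; default 1.
#' @param log_eps floor added to the magnitude before `log10`; default 1e-10.
#' @param rate sample rate, only needed when `x` is a bare numeric vector.
#' @return A normalized [sm_surface] of size `grid_N x grid_N`.
#' @export
compute_surface <- function(x, kind = c("stft", "mel"), stft_params = list(),
                            grid_N = 64L, alpha = 1, log_eps = 1e-10,
                            rate = NULL) {
  kind <- match.arg(kind)
  sig <- if (inherits(x, "sm_signal")) x else as_sm_signal(x, rate)
  n <- length(sig$samples)
  grid_N <- as.integer(grid_N)
  if (grid_N < 2L) stop("grid_N must be >= 2")

  overlap <- stft_params$overlap %||% 0.75
  window <- stft_params$window
  if (is.null(window)) {
    # aim for ~4x frequency oversampling of the target grid (window/2 + 1
    # bins vs grid_N rows), shrunk if the signal is too short for grid_N
    # frames at this overlap
    window <- 2^round(log2(8 * grid_N))
    window <- max(8L, min(1024L, as.integer(window)))
    while (window > 8L &&
           (n < window ||
            (n - window) %/% max(1L, as.integer((1 - overlap) * window)) +
              1L < grid_N)) {
      window <- window %/% 2L
    }
  }
  hop <- max(1L, as.integer(floor((1 - overlap) * window)))
  frames <- if (n >= window) (n - window) %/% hop + 1L else 0L
  if (frames < grid_N) {
    stop(sprintf(
      "signal too short: %d samples gives %d frames < grid_N = %d (need >= %d samples at window %d)",
      n, frames, grid_N, window + (grid_N - 1L) * hop, window))
  }

  sp <- stft_magnitude(sig$samples, sig$rate, window, overlap)
  if (kind == "mel") {
    n_mels <- stft_params$n_mels %||% 64L
    mf <- mel_filterbank(sp$f, n_mels)
    mag <- mf$fb %*% sp$mag
    f_axis <- mf$centers
  } else {
    mag <- sp$mag
    f_axis <- sp$f
  }
  z <- log10(mag + log_eps)

  # z comes as (freq x time); the surface stores (time x freq)
  dst_t <- seq(min(sp$t), max(sp$t), length.out = grid_N)
  dst_f <- seq(min(f_axis), max(f_axis), length.out = grid_N)
  zg <- resample_grid(t(z), sp$t, f_axis, dst_t, dst_f)

  raw <- sm_surface(dst_t, dst_f, zg,
                    scale_meta = list(
                      kind = kind, window = window, overlap = overlap,
                      magnitude_transform = sprintf("log10(mag + %g)", log_eps),
                      rate = sig$rate, id = sig$id))
  normalize_surface(raw, alpha = alpha)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a surface as plain text
#'
#' The z matrix is written as a whitespace-separated text table and the axes
#' plus `scale_meta` as a JSON sidecar (`<path>.json`).
#'
#' @param s a [sm_surface].
#' @param path file path for the z matrix.
#' @return `write_surface()` returns `path` invisibly; `read_surface()`
#'   returns the [sm_surface].
#' @export
write_surface <- function(s, path) {
  stopifnot(inherits(s, "sm_surface"))
  utils::write.table(s$z, path, row.names = FALSE, col.names = FALSE)
  side <- list(times = s$times, freqs = s$freqs, scale_meta = s$scale_meta)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  z <- as.matrix(utils::read.table(path))
  dimnames(z) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sm_surface(side$times, side$freqs, z, as.list(side$scale_meta))
}
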