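#' MFCC trajectory statistics (72-feature baseline)
#'
#' Extracts `n_mfcc` mel-frequency cepstral coefficients per analysis frame
#' (log mel-filterbank energies followed by an orthonormal DCT-II, keeping
#' coefficients 1..`n_mfcc` and dropping the 0th, energy-like, term), then
#' summarizes each coefficient trajectory with six statistics: mean,
#' standard deviation, min, max, mean of the absolute successive
#' difference, and standard deviation of the absolute successive
#' difference. With the default 12 coefficients this yields the classical
#' 72-dimensional baseline feature vector. Feature order is
#' coefficient-major: `mfcc01_mean, mfcc01_sd, ..., mfcc12_sd_absdiff`.
#'
#' @param x a [sm_signal] or numeric vector.
#' @param n_mfcc number of cepstral coefficients; default 12.
#' @param n_mels mel filterbank size; default 26.
#' @param window STFT window length in samples (default 512, shortened for
#'   short signals).
#' @param overlap STFT window overlap fraction; default 0.5.
#' @param rate sample rate when `x` is a bare vector.
#' @return Named numeric vector of `6 * n_mfcc` features.
#' @export
mfcc_features <- function(x, n_mfcc = 12L, n_mels = 26L, window = 512L,
                          overlap = 0.5, rate = NULL) {
  sig <- if (inherits(x, "sm_signal")) x else as_sm_signal(x, rate)
  n <- length(sig$samples)
  window <- min(window, 2^floor(log2(n / 2)))
  hop <- max(1L, as.integer((1 - overlap) * window))
  if (window < 64L || n < window + hop) {
    stop(sprintf("signal too short for MFCC: %d samples (need >= %d)", n,
                 max(128L, window + hop)))
  }
  cc <- mfcc_frames(sig$samples, sig$rate, n_mfcc, n_mels, window, overlap)
  out <- as.vector(apply(cc, 1L, trajectory_stats))
  names(out) <- as.vector(t(outer(
    sprintf("mfcc%02d", seq_len(n_mfcc)),
    c("mean", "sd", "min", "max", "mean_absdiff", "sd_absdiff"),
    paste, sep = "_")))
  out
}

# per-frame cepstral coefficients, one column per frame
mfcc_frames <- function(samples, rate, n_mfcc, n_mels, window, overlap) {
  sp <- stft_magnitude(samples, rate, window, overlap)
  mf <- mel_filterbank(sp$f, n_mels)
  logmel <- log(mf$fb %*% (sp$mag^2) + 1e-10)
  # orthonormal DCT-II rows 2..(n_mfcc + 1): drop the 0th coefficient
  k <- seq_len(n_mfcc)
  j <- seq_len(n_mels) - 0.5
  D <- sqrt(2 / n_mels) * cos(pi / n_mels * outer(k, j))
  D %*% logmel
}

#' Six summary statistics of a coefficient trajectory
#'
#' @param v numeric vector (one MFCC trajectory over frames).
#' @return `c(mean, sd, min, max, mean_absdiff, sd_absdiff)`; the
#'   difference-based statistics use the absolute successive differences
#'   `|v[i+1] - v[i]|`. `sd` terms are 0 for length-1 inputs.
#' @export
trajectory_stats <- function(v) {
  ad <- abs(diff(v))
  sd0 <- function(u) if (length(u) < 2L) 0 else stats::sd(u)
  c(mean(v), sd0(v), min(v), max(v),
    if (length(ad)) mean(ad) else 0, sd0(ad))
}
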