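#' Define a synthetic signal class
#'
#' Describes one class of synthetic recordings as a parameterized mixture of
#' an amplitude-modulated (possibly chirped) carrier, band-limited noise and
#' white noise at a stated SNR. Classes with disjoint carrier bands produce
#' spectrogram surfaces with geometrically distinct ridges, which is what
#' the distortion signature is designed to separate.
#'
#' @param carrier_hz length-2 range (Hz) the carrier frequency is drawn from.
#' @param chirp_hz_s linear chirp rate (Hz/s) applied to the carrier.
#' @param am_depth amplitude-modulation depth in `[0, 1]`.
#' @param am_hz amplitude-modulation frequency (Hz).
#' @param noise_band_hz optional length-2 band (Hz) of added band-limited
#'   noise; `NULL` for none.
#' @param snr_db signal-to-noise ratio of the added white noise (dB);
#'   `Inf` for a clean signal.
#' @return A list of class `sm_class_def`.
#' @export
class_def <- function(carrier_hz, chirp_hz_s = 0, am_depth = 0, am_hz = 4,
                      noise_band_hz = NULL, snr_db = 10) {
  carrier_hz <- as.numeric(carrier_hz)
  if (length(carrier_hz) == 1L) carrier_hz <- rep(carrier_hz, 2L)
  stopifnot(length(carrier_hz) == 2L, all(carrier_hz > 0),
            carrier_hz[1] <= carrier_hz[2],
            am_depth >= 0, am_depth <= 1, am_hz > 0)
  if (!is.null(noise_band_hz)) {
    stopifnot(length(noise_band_hz) == 2L, noise_band_hz[1] < noise_band_hz[2],
              noise_band_hz[1] >= 0)
  }
  if (!(snr_db > -Inf)) stop("snr_db must be > -Inf")
  structure(list(carrier_hz = carrier_hz, chirp_hz_s = chirp_hz_s,
                 am_depth = am_depth, am_hz = am_hz,
                 noise_band_hz = noise_band_hz, snr_db = snr_db),
            class = "sm_class_def")
}

#' Specification for a synthetic labelled corpus
#'
#' @param classes named list of [class_def()] objects; names become class
#'   labels.
#' @param n_per_class recordings per class.
#' @param groups_per_class distinct subject (group) labels per class;
#'   recordings are assigned to groups round-robin so grouped splitting is
#'   always exercised.
#' @param duration recording length in seconds.
#' @param rate sample rate in Hz.
#' @param seed integer seed making generation fully reproducible.
#' @return A list of class `sm_synth_spec`.
#' @export
synthetic_spec <- function(classes, n_per_class = 20L, groups_per_class = 5L,
                           duration = 2, rate = 4000, seed = 1L) {
  stopifnot(is.list(classes), length(classes) >= 1L,
            !is.null(names(classes)), all(nzchar(names(classes))))
  for (cd in classes) stopifnot(inherits(cd, "sm_class_def"))
  n_per_class <- as.integer(n_per_class)
  groups_per_class <- as.integer(groups_per_class)
  stopifnot(n_per_class >= 1L, groups_per_class >= 1L,
            duration > 0, rate > 0)
  nyq <- rate / 2
  for (nm in names(classes)) {
    cd <- classes[[nm]]
    fmax <- cd$carrier_hz[2] + abs(cd$chirp_hz_s) * duration
    if (fmax >= nyq) {
      stop(sprintf("class '%s' exceeds the Nyquist frequency %g Hz", nm, nyq))
    }
  }
  structure(list(classes = classes, n_per_class = n_per_class,
                 groups_per_class = groups_per_class, duration = duration,
                 rate = rate, seed = as.integer(seed)),
            class = "sm_synth_spec")
}

synth_one <- function(cd, duration, rate, f0) {
  t <- seq(0, duration, by = 1 / rate)[- (duration * rate + 1L)]
  phase <- 2 * pi * (f0 * t + cd$chirp_hz_s * t^2 / 2)
  env <- 1 + cd$am_depth * sin(2 * pi * cd$am_hz * t)
  x <- env * sin(phase)
  if (!is.null(cd$noise_band_hz)) {
    bf <- signal::butter(4, cd$noise_band_hz / (rate / 2), type = "pass")
    bn <- signal::filtfilt(bf, stats::rnorm(length(t)))
    # band noise at fixed -6 dB relative to the carrier component
    bn <- bn / stats::sd(bn) * stats::sd(x) * 10^(-6 / 20)
    x <- x + bn
  }
  if (is.finite(cd$snr_db)) {
    noise <- stats::rnorm(length(t))
    noise <- noise / stats::sd(noise) * stats::sd(x) * 10^(-cd$snr_db / 20)
    x <- x + noise
  }
  x
}

#' Generate a seeded synthetic labelled corpus
#'
#' Produces `n_per_class` recordings for every class in the spec, each the
#' sum of that class's parameterized components plus white noise at the
#' stated SNR. Carrier frequencies are drawn uniformly from the class band.
#' Group (subject) labels are assigned round-robin within each class.
#' Generation is deterministic: the same spec yields identical sample
#' streams.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `signals` (list of [sm_signal]) and `labels` (a
#'   data.frame with columns `id`, `group`, `class`).
#' @export
generate_signals <- function(spec) {
  stopifnot(inherits(spec, "sm_synth_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  signals <- list()
  rows <- list()
  for (nm in names(spec$classes)) {
    cd <- spec$classes[[nm]]
    for (k in seq_len(spec$n_per_class)) {
      g <- ((k - 1L) %% spec$groups_per_class) + 1L
      id <- sprintf("%s_%03d", nm, k)
      group <- sprintf("%s_subj%02d", nm, g)
      f0 <- stats::runif(1, cd$carrier_hz[1], cd$carrier_hz[2])
      x <- synth_one(cd, spec$duration, spec$rate, f0)
      signals[[id]] <- sm_signal(x, spec$rate, id = id, group = group)
      rows[[id]] <- data.frame(id = id, group = group, class = nm)
    }
  }
  labels <- do.call(rbind, rows)
  rownames(labels) <- NULL
  list(signals = signals, labels = labels)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a height-field mesh fixture
#'
#' Builds the standard grid mesh over the unit square with a controlled
#' height law: `flat` (constant z), `gaussian_bumps` (sum of `n_bumps`
#' random Gaussian bumps) or `random` (smooth random field from a
#' low-order random Fourier series, so triangles stay well shaped).
#' Deterministic per seed.
#'
#' @param kind `"flat"`, `"gaussian_bumps"` or `"random"`.
#' @param N grid resolution per axis (>= 2).
#' @param amplitude peak height scale; default 0.3.
#' @param seed integer seed.
#' @param n_bumps number of Gaussian bumps for `kind = "gaussian_bumps"`.
#' @return A [sm_trimesh].
#' @export
generate_height_field_mesh <- function(kind = c("flat", "gaussian_bumps",
                                                "random"),
                                       N = 32L, amplitude = 0.3, seed = 1L,
                                       n_bumps = 4L) {
  kind <- match.arg(kind)
  N <- as.integer(N)
  if (N < 2L) stop("N must be >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  g <- seq(0, 1, length.out = N)
  X <- matrix(rep(g, times = N), N)   # x varies along rows
  Y <- matrix(rep(g, each = N), N)
  z <- switch(kind,
    flat = matrix(0, N, N),
    gaussian_bumps = {
      zz <- matrix(0, N, N)
      for (b in seq_len(n_bumps)) {
        cx <- stats::runif(1, 0.2, 0.8); cy <- stats::runif(1, 0.2, 0.8)
        w <- stats::runif(1, 0.05, 0.2)
        a <- stats::runif(1, 0.5, 1) * amplitude
        zz <- zz + a * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * w^2))
      }
      zz
    },
    random = {
      zz <- matrix(0, N, N)
      for (kx in 0:3) for (ky in 0:3) {
        if (kx + ky == 0) next
        zz <- zz + stats::rnorm(1) / (kx + ky) *
          cos(pi * (kx * X + stats::runif(1))) *
          cos(pi * (ky * Y + stats::runif(1)))
      }
      zz / max(abs(zz)) * amplitude
    })
  sm_trimesh(cbind(as.vector(X), as.vector(Y), as.vector(z)),
             build_mesh(sm_surface(g, g, matrix(0, N, N)))$F)
}

#' Stock synthetic scenarios
#'
#' Ready-made corpus specifications exercising the experiment shapes the
#' package targets: `lung_like_spec()` mimics the gross structure of
#' auscultation classes (low-frequency narrowband "wheeze"-like tones vs.
#' broadband transient "crackle"-like activity vs. near-noise "healthy"
#' breath sounds), and `speech_like_spec()` mimics accent-style classes as
#' formant-band chirp mixtures. `tonal_vs_broadband_spec()` is the
#' two-class geometric benchmark: a clean amplitude-modulated tone (smooth,
#' nearly developable spectrogram surface) against noisy broadband activity
#' (rough, strongly curved surface), i.e. classes separable by surface
#' geometry by construction. Parameters are illustrative stand-ins for real
#' corpora, not acoustic models of pathology or accent.
#'
#' @param n_per_class,groups_per_class,seed passed to [synthetic_spec()].
#' @return A [synthetic_spec()].
#' @export
lung_like_spec <- function(n_per_class = 20L, groups_per_class = 5L,
                           seed = 1L) {
  synthetic_spec(
    classes = list(
      wheeze = class_def(c(200, 400), am_depth = 0.6, am_hz = 2,
                         snr_db = 12),
      crackle = class_def(c(700, 900), am_depth = 0.9, am_hz = 12,
                          noise_band_hz = c(600, 1100), snr_db = 8),
      healthy = class_def(c(80, 150), am_depth = 0.2, am_hz = 1,
                          noise_band_hz = c(50, 600), snr_db = 5)
    ),
    n_per_class = n_per_class, groups_per_class = groups_per_class,
    duration = 2, rate = 4000, seed = seed)
}

#' @rdname lung_like_spec
#' @export
tonal_vs_broadband_spec <- function(n_per_class = 60L, groups_per_class = 12L,
                                    seed = 1L) {
  synthetic_spec(
    classes = list(
      tonal = class_def(c(300, 600), am_depth = 0.5, am_hz = 3,
                        snr_db = 25),
      broadband = class_def(c(700, 1000), am_depth = 0.9, am_hz = 12,
                            noise_band_hz = c(400, 1600), snr_db = 5)
    ),
    n_per_class = n_per_class, groups_per_class = groups_per_class,
    duration = 1.5, rate = 4000, seed = seed)
}

#' @rdname lung_like_spec
#' @export
speech_like_spec <- function(n_per_class = 20L, groups_per_class = 5L,
                             seed = 1L) {
  synthetic_spec(
    classes = list(
      accent_a = class_def(c(300, 500), chirp_hz_s = 150, am_depth = 0.4,
                           am_hz = 5, snr_db = 10),
      accent_b = class_def(c(900, 1200), chirp_hz_s = -200, am_depth = 0.4,
                           am_hz = 5, snr_db = 10)
    ),
    n_per_class = n_per_class, groups_per_class = groups_per_class,
    duration = 1.5, rate = 8000, seed = seed)
}
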