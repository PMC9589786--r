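#' Closed-form local distortion energies
#'
#' Each energy is a function of the two singular values `sigma1 >= sigma2 >
#' 0` of the per-triangle Jacobian of a planar parametrization, scoring how
#' the triangle is deformed:
#'
#' * **Isometric** (length) distortions: `arap` = `(s1^2 - 1)^2 +
#'   (s2^2 - 1)^2`; `symmetric_dirichlet` = `(s1^2 + s1^-2 + s2^2 + s2^-2) /
#'   4`; `qi` (quasi-isometric dilatation) = `max(s1, 1/s2)`.
#' * **Conformal** (angle) distortions: `qc` (quasi-conformal dilatation) =
#'   `max(s1/s2, s2/s1)`; `mips` = `s1/s2 + s2/s1`.
#' * **Area** distortion: `ad` (unsigned) = `max(|s1 s2|, 1/|s1 s2|)`.
#' * **Scale** distortions: `dirichlet` = `(s1^2 + s2^2) / 2`; `cf`
#'   (conformal factor) = `(s1 + s2) / 2`.
#'
#' All eight are invariant to rigid motions of the source surface. Lower
#' bounds: `arap >= 0`, `symmetric_dirichlet >= 1`, `qi >= 1`, `qc >= 1`,
#' `mips >= 2`, `ad >= 1`, `dirichlet > 0`, `cf > 0`; the isometric, area
#' and `sd` bounds are attained exactly at `s1 = s2 = 1`, the conformal
#' bounds whenever `s1 = s2`.
#'
#' @format A named list of vectorized functions `E(sigma1, sigma2)`.
#' @export
energy_registry <- list(
  arap = function(s1, s2) (s1^2 - 1)^2 + (s2^2 - 1)^2,
  symmetric_dirichlet = function(s1, s2) (s1^2 + s1^-2 + s2^2 + s2^-2) / 4,
  qi = function(s1, s2) pmax(s1, 1 / s2),
  qc = function(s1, s2) pmax(s1 / s2, s2 / s1),
  mips = function(s1, s2) s1 / s2 + s2 / s1,
  ad = function(s1, s2) pmax(abs(s1 * s2), 1 / abs(s1 * s2)),
  dirichlet = function(s1, s2) (s1^2 + s2^2) / 2,
  cf = function(s1, s2) (s1 + s2) / 2
)

#' Evaluate a named distortion energy
#'
#' @param name one of `names(energy_registry)`.
#' @param sigma1,sigma2 singular values with `sigma1 >= sigma2 > 0`
#'   (vectorized).
#' @return Numeric vector of energy values.
#' @examples
#' evaluate_energy("symmetric_dirichlet", 2, 1)  # 1.5625
#' evaluate_energy("mips", 2, 1)                 # 2.5
#' @export
evaluate_energy <- function(name, sigma1, sigma2) {
  f <- energy_registry[[name]]
  if (is.null(f)) {
    stop(sprintf("unknown energy '%s' (available: %s)", name,
                 paste(names(energy_registry), collapse = ", ")))
  }
  if (any(sigma2 <= 0)) {
    stop("sigma2 <= 0: the map is invalid (inverted or collapsed triangle)")
  }
  if (any(sigma1 < sigma2)) stop("sigma1 must be >= sigma2")
  f(sigma1, sigma2)
}

#' Split mesh triangles into low/high frequency bands
#'
#' Computes the median of the per-triangle centroid frequencies `f_cg` and
#' partitions the triangle set: band 1 holds triangles with `f_cg` strictly
#' below the median, band 2 those with `f_cg >=` the median. With constant
#' `f_cg` band 1 is empty (flagged with a warning by downstream consumers).
#'
#' @param mesh a [sm_trimesh] with at least 2 triangles.
#' @return A list with `median_f`, `band1`, `band2` (integer triangle
#'   indices).
#' @export
split_by_frequency <- function(mesh) {
  stopifnot(inherits(mesh, "sm_trimesh"))
  if (nrow(mesh$F) < 2L) stop("mesh must have at least 2 triangles")
  fcg <- triangle_fcg(mesh)
  med <- stats::median(fcg)
  list(median_f = med,
       band1 = which(fcg < med),
       band2 = which(fcg >= med))
}

#' Area-weighted global distortion over a triangle subset
#'
#' The global distortion of a map with respect to a local energy `E` over a
#' triangle subset is `sum(E(t) * area(t)) / sum(area(t))`, with `area(t)`
#' the source-surface (3D) triangle area, so the weighting reflects the
#' signal's own geometry rather than the map being scored.
#'
#' @param energy_values per-triangle energy values.
#' @param areas per-triangle positive source areas.
#' @param subset integer indices of the subset (default: all triangles).
#' @return The area-weighted mean; `NA_real_` with a warning for an empty
#'   subset.
#' @export
global_distortion <- function(energy_values, areas,
                              subset = seq_along(energy_values)) {
  if (length(energy_values) != length(areas)) {
    stop("energy_values and areas must have equal length")
  }
  if (any(areas[subset] <= 0)) stop("areas must be positive")
  if (length(subset) == 0L) {
    warning("empty triangle subset: global distortion undefined")
    return(NA_real_)
  }
  sum(energy_values[subset] * areas[subset]) / sum(areas[subset])
}

#' Names of the 16 signature features
#'
#' Fixed feature ordering of the distortion signature: energy-major,
#' band-minor (`E_arap_1, E_arap_2, E_symmetric_dirichlet_1, ...`).
#'
#' @return Character vector of length 16.
#' @export
signature_feature_names <- function() {
  as.vector(t(outer(names(energy_registry), 1:2,
                    function(e, b) sprintf("E_%s_%d", e, b))))
}

#' Extract the 16-dimensional distortion signature
#'
#' Evaluates all eight local distortion energies on the embedding's signed
#' singular values and aggregates each by area-weighted averaging over the
#' low- and high-frequency triangle bands (see [split_by_frequency()]),
#' yielding the 16-vector used as the shape descriptor of the spectrogram
#' surface. If the low band is empty (constant triangle frequency), its 8
#' features are set to the full-mesh global distortions and a warning is
#' raised, so the signature stays a well-defined 16-vector.
#'
#' @param mesh a [sm_trimesh].
#' @param emb a valid `sm_embedding` (all `det df_t > 0`).
#' @return Named numeric vector of length 16 (see
#'   [signature_feature_names()]) with attribute `provenance` recording the
#'   flattening configuration.
#' @export
extract_signature <- function(mesh, emb) {
  stopifnot(inherits(mesh, "sm_trimesh"), inherits(emb, "sm_embedding"))
  if (any(emb$det <= 0)) {
    stop("embedding contains inverted triangles; signature undefined")
  }
  areas <- triangle_areas(mesh)
  sp <- split_by_frequency(mesh)
  bands <- list(sp$band1, sp$band2)
  empty_low <- length(sp$band1) == 0L
  if (empty_low) {
    warning("constant triangle frequency: low band empty, ",
            "using full-mesh distortions for band-1 features")
    bands[[1L]] <- seq_len(nrow(mesh$F))
  }
  out <- numeric(0)
  for (en in names(energy_registry)) {
    ev <- evaluate_energy(en, emb$sigma1, emb$sigma2)
    for (b in 1:2) {
      out <- c(out, global_distortion(ev, areas, bands[[b]]))
    }
  }
  names(out) <- signature_feature_names()
  attr(out, "provenance") <- provenance_hash(emb$config)
  out
}

# stable short hash of the flattening configuration
provenance_hash <- function(cfg) {
  if (is.null(cfg)) return("tutte-init")
  s <- paste(names(unclass(cfg)), vapply(unclass(cfg), format, ""),
             sep = "=", collapse = ";")
  # small rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("cfg-%08x", as.integer(h))
}

#' Distortion signature of a signal
#'
#' End-to-end convenience: surface, mesh, flattening, signature.
#'
#' @param x a [sm_signal].
#' @param kind spectrogram kind, `"stft"` or `"mel"`.
#' @param grid_N surface grid resolution.
#' @param alpha surface z aspect factor.
#' @param cfg a [flatten_config()].
#' @param ... passed to [compute_surface()].
#' @return Named numeric vector of 16 features.
#' @export
signal_signature <- function(x, kind = "stft", grid_N = 32L, alpha = 1,
                             cfg = flatten_config(), ...) {
  surf <- compute_surface(x, kind = kind, grid_N = grid_N, alpha = alpha, ...)
  mesh <- build_mesh(surf)
  emb <- flatten_mesh(mesh, cfg)
  extract_signature(mesh, emb)
}
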