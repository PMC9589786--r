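#' Flattening configuration
#'
#' Controls the distortion-minimizing planar parametrization. The
#' optimization starts from a bijective Tutte (convex-combination) embedding
#' and performs monotone, flip-free descent of a barrier distortion energy:
#' every line-search step is capped strictly below the smallest step that
#' would collapse a triangle (`step_cap_factor` times the nearest root of
#' `det df_t = 0` along the descent direction), so local injectivity of the
#' initialization is preserved at every accepted iterate.
#'
#' @param optimized_energy energy to minimize: `"symmetric_dirichlet"`
#'   (default; isometric barrier) or `"mips"` (conformal barrier). With
#'   `boundary = "free"` only barrier energies are admissible, since a
#'   non-barrier objective could drive triangles to collapse.
#' @param max_iters maximum number of descent iterations (default 2000).
#' @param grad_tolerance stop when the max-norm of the energy gradient falls
#'   below this (default 1e-8).
#' @param energy_tolerance stop when the relative per-iteration energy
#'   decrease falls below this; default 0 (disabled), because descent can
#'   pass through near-flat plateaus long before the gradient is small, and
#'   the line search already stops the run when no representable decrease is
#'   left.
#' @param line_search_shrink backtracking shrink factor in (0, 1), default 0.5.
#' @param step_cap_factor fraction of the nearest flip step used as the
#'   maximum line-search step, default 0.9.
#' @param boundary `"free"` (default) or `"fixed"` (boundary pinned to its
#'   initial positions).
#' @param preconditioner `"sobolev"` (default; descent direction obtained by
#'   solving against the source-mesh cotangent Laplacian, the Hessian of the
#'   Dirichlet part of the energy) or `"diagonal"` (its diagonal only).
#' @param weights Tutte convex-combination weights: `"mean_value"` (default)
#'   or `"uniform"`.
#' @return An object of class `sm_flatten_config`.
#' @export
flatten_config <- function(optimized_energy = "symmetric_dirichlet",
                           max_iters = 2000L,
                           grad_tolerance = 1e-8,
                           energy_tolerance = 0,
                           line_search_shrink = 0.5,
                           step_cap_factor = 0.9,
                           boundary = c("free", "fixed"),
                           preconditioner = c("sobolev", "diagonal"),
                           weights = c("mean_value", "uniform")) {
  boundary <- match.arg(boundary)
  preconditioner <- match.arg(preconditioner)
  weights <- match.arg(weights)
  barrier <- c("symmetric_dirichlet", "mips")
  if (!optimized_energy %in% barrier) {
    stop(sprintf("unknown or non-barrier optimized_energy '%s' (available: %s)",
                 optimized_energy, paste(barrier, collapse = ", ")))
  }
  stopifnot(line_search_shrink > 0, line_search_shrink < 1,
            step_cap_factor > 0, step_cap_factor < 1)
  structure(list(optimized_energy = optimized_energy,
                 max_iters = as.integer(max_iters),
                 grad_tolerance = grad_tolerance,
                 energy_tolerance = energy_tolerance,
                 line_search_shrink = line_search_shrink,
                 step_cap_factor = step_cap_factor,
                 boundary = boundary,
                 preconditioner = preconditioner,
                 weights = weights),
            class = "sm_flatten_config")
}

# Per-triangle local orthonormal frame and inverse source-edge matrix.
# Frame: first axis along edge p1 - p0, second completing a right-handed
# frame with the upward-oriented triangle normal. Returns the entries of
# Pinv = P^{-1} where P = [e1 | e2] in frame coordinates (upper triangular).
triangle_frames <- function(mesh) {
  V <- mesh$V; F <- mesh$F
  E1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  E2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  l1 <- sqrt(rowSums(E1^2))
  if (any(l1 == 0)) {
    stop(sprintf("degenerate source triangle %d (zero-length edge)",
                 which(l1 == 0)[1L]))
  }
  nx <- E1[, 2] * E2[, 3] - E1[, 3] * E2[, 2]
  ny <- E1[, 3] * E2[, 1] - E1[, 1] * E2[, 3]
  nz <- E1[, 1] * E2[, 2] - E1[, 2] * E2[, 1]
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  if (any(nn == 0)) {
    stop(sprintf("degenerate source triangle %d (zero area)",
                 which(nn == 0)[1L]))
  }
  # P = [[l1, E2.e1], [0, E2.e2]];  E2.e2 = 2 area / l1 > 0
  p11 <- l1
  p12 <- rowSums(E1 * E2) / l1
  p22 <- nn / l1
  det <- p11 * p22
  list(i11 = p22 / det, i12 = -p12 / det, i21 = rep(0, nrow(F)),
       i22 = p11 / det, area = nn / 2)
}

# J = Q %*% Pinv for all triangles, given uv (n x 2); entries (a b; c d)
jacobian_entries <- function(F, uv, fr) {
  q1x <- uv[F[, 2], 1] - uv[F[, 1], 1]
  q1y <- uv[F[, 2], 2] - uv[F[, 1], 2]
  q2x <- uv[F[, 3], 1] - uv[F[, 1], 1]
  q2y <- uv[F[, 3], 2] - uv[F[, 1], 2]
  list(a = q1x * fr$i11 + q2x * fr$i21,
       b = q1x * fr$i12 + q2x * fr$i22,
       c = q1y * fr$i11 + q2y * fr$i21,
       d = q1y * fr$i12 + q2y * fr$i22)
}

signed_svd_2x2 <- function(a, b, c, d) {
  e <- (a + d) / 2; h <- (c - b) / 2
  f <- (a - d) / 2; g <- (c + b) / 2
  q1 <- sqrt(e^2 + h^2); q2 <- sqrt(f^2 + g^2)
  list(s1 = q1 + q2, s2 = q1 - q2)  # s2 carries the sign of det
}

#' Per-triangle Jacobians and signed singular values of a planar map
#'
#' For each triangle, a right-handed orthonormal frame is erected in the 3D
#' triangle's plane (first axis along the edge `p1 - p0`, second completing
#' the frame with the upward-oriented normal); the Jacobian `df_t` is the
#' unique 2x2 linear map sending the frame coordinates of the source edges
#' to the corresponding planar (uv) edges. Because the frame is intrinsic to
#' the triangle, the singular values are invariant to rigid motions of the
#' source mesh. The second singular value is signed: `sigma2 < 0` iff
#' `det df_t < 0`, i.e. the triangle is inverted in the plane.
#'
#' @param mesh a [sm_trimesh].
#' @param uv numeric `n x 2` matrix of planar vertex positions.
#' @return A list with per-triangle vectors `sigma1`, `sigma2`, `det`,
#'   `area` (source 3D area) and the matrix `J` (`m x 4`, columns `a, b, c,
#'   d` of `[[a, b], [c, d]]`).
#' @export
triangle_jacobians <- function(mesh, uv) {
  stopifnot(inherits(mesh, "sm_trimesh"))
  uv <- as.matrix(uv)
  dimnames(uv) <- NULL
  if (nrow(uv) != nrow(mesh$V) || ncol(uv) != 2L) {
    stop("uv must be n x 2 with one row per mesh vertex")
  }
  fr <- triangle_frames(mesh)
  jj <- jacobian_entries(mesh$F, uv, fr)
  sv <- signed_svd_2x2(jj$a, jj$b, jj$c, jj$d)
  list(sigma1 = sv$s1, sigma2 = sv$s2,
       det = jj$a * jj$d - jj$b * jj$c,
       area = fr$area,
       J = cbind(a = jj$a, b = jj$b, c = jj$c, d = jj$d))
}

new_embedding <- function(mesh, uv, energy_trace, config = NULL,
                          converged = NA) {
  tj <- triangle_jacobians(mesh, uv)
  structure(list(uv = uv, sigma1 = tj$sigma1, sigma2 = tj$sigma2,
                 det = tj$det, energy_trace = energy_trace,
                 config = config, converged = converged),
            class = "sm_embedding")
}

#' @export
print.sm_embedding <- function(x, ...) {
  cat(sprintf(
    "<sm_embedding: %d vertices, %d triangles, %d flipped, sigma in [%.4g, %.4g]>\n",
    nrow(x$uv), length(x$sigma1), sum(x$det <= 0),
    min(x$sigma2), max(x$sigma1)))
  invisible(x)
}

# mean-value or uniform convex-combination weights as a sparse matrix W
# (W[i, j] > 0 iff j is a neighbor of i)
tutte_weights <- function(mesh, weights) {
  V <- mesh$V; F <- mesh$F
  n <- nrow(V)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  corners <- list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
  for (co in corners) {
    v0 <- F[, co[1L]]; v1 <- F[, co[2L]]; v2 <- F[, co[3L]]
    if (weights == "uniform") {
      ii <- c(ii, v0, v0); jj <- c(jj, v1, v2)
      ww <- c(ww, rep(0.5, 2L * nrow(F)))  # each edge seen from 2 triangles
    } else {
      e1 <- V[v1, , drop = FALSE] - V[v0, , drop = FALSE]
      e2 <- V[v2, , drop = FALSE] - V[v0, , drop = FALSE]
      l1 <- sqrt(rowSums(e1^2)); l2 <- sqrt(rowSums(e2^2))
      cosa <- pmin(1, pmax(-1, rowSums(e1 * e2) / (l1 * l2)))
      t2 <- tan(acos(cosa) / 2)  # tan of half the corner angle at v0
      ii <- c(ii, v0, v0); jj <- c(jj, v1, v2)
      ww <- c(ww, t2 / l1, t2 / l2)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
}

#' Tutte (convex-combination) embedding of a disk mesh
#'
#' Places the boundary loop on the unit circle, spaced proportionally to the
#' 3D boundary edge lengths, and positions every interior vertex at a convex
#' combination of its neighbors by solving the sparse linear system. With a
#' convex boundary and positive weights the resulting piecewise-affine map
#' is bijective: every triangle keeps positive orientation (`det df_t > 0`).
#'
#' @param mesh a disk-topology [sm_trimesh].
#' @param weights `"mean_value"` (default) or `"uniform"`.
#' @return An `sm_embedding` with fields `uv`, signed singular values
#'   `sigma1`/`sigma2`, `det` and a one-entry `energy_trace`.
#' @export
tutte_embed <- function(mesh, weights = c("mean_value", "uniform")) {
  weights <- match.arg(weights)
  loop <- boundary_loop(mesh)
  n <- nrow(mesh$V)
  nb <- length(loop)

  # boundary on the unit circle, arcs proportional to 3D edge lengths
  P <- mesh$V[loop, , drop = FALSE]
  seg <- sqrt(rowSums((P[c(2:nb, 1L), ] - P)^2))
  theta <- 2 * pi * c(0, cumsum(seg)[-nb]) / sum(seg)
  uv <- matrix(NA_real_, n, 2L)
  uv[loop, ] <- cbind(cos(theta), sin(theta))

  interior <- setdiff(seq_len(n), loop)
  if (length(interior) > 0L) {
    W <- tutte_weights(mesh, weights)
    rs <- Matrix::rowSums(W)
    L <- Matrix::Diagonal(n, rs) - W
    A <- L[interior, interior, drop = FALSE]
    B <- -L[interior, loop, drop = FALSE]
    sol <- tryCatch(
      as.matrix(Matrix::solve(A, B %*% uv[loop, , drop = FALSE])),
      error = function(e) stop("topology error: singular Tutte system (",
                               conditionMessage(e), ")"))
    uv[interior, ] <- sol
  }
  emb <- new_embedding(mesh, uv, energy_trace = NULL)
  fr <- triangle_frames(mesh)
  jj <- jacobian_entries(mesh$F, uv, fr)
  e0 <- opt_energy_value("symmetric_dirichlet", jj, fr$area)
  emb$energy_trace <- data.frame(iteration = 0L, energy = e0,
                                 min_det = min(emb$det))
  emb
}

# --- barrier energies for optimization: value and gradient wrt J ----------

# symmetric Dirichlet: (|J|_F^2 + |J^{-1}|_F^2) / 4, area-weighted total
opt_energy_value <- function(name, jj, area) {
  det <- jj$a * jj$d - jj$b * jj$c
  if (any(det <= 0)) return(Inf)
  fro2 <- jj$a^2 + jj$b^2 + jj$c^2 + jj$d^2
  per <- switch(name,
    symmetric_dirichlet = (fro2 + fro2 / det^2) / 4,
    mips = fro2 / det)
  sum(per * area)
}

opt_energy_grad <- function(name, jj, area) {
  a <- jj$a; b <- jj$b; c <- jj$c; d <- jj$d
  det <- a * d - b * c
  fro2 <- a^2 + b^2 + c^2 + d^2
  # adjugate-transpose entries: d(det)/d(a,b,c,d) = (d, -c, -b, a)
  if (name == "symmetric_dirichlet") {
    # dE/dJ = (J + J/det^2 - fro2/det^3 * adjT) / 2
    k <- fro2 / det^3
    ga <- (a + a / det^2 - k * d) / 2
    gb <- (b + b / det^2 + k * c) / 2
    gc <- (c + c / det^2 + k * b) / 2
    gd <- (d + d / det^2 - k * a) / 2
  } else {  # mips: fro2 / det
    ga <- 2 * a / det - fro2 / det^2 * d
    gb <- 2 * b / det + fro2 / det^2 * c
    gc <- 2 * c / det + fro2 / det^2 * b
    gd <- 2 * d / det - fro2 / det^2 * a
  }
  list(a = ga * area, b = gb * area, c = gc * area, d = gd * area)
}

# scatter per-triangle dE/dQ to per-vertex gradient (n x 2)
scatter_gradient <- function(F, n, gq, fr) {
  # dE/dQ = dE/dJ %*% t(Pinv); Q columns are (uv2 - uv1), (uv3 - uv1)
  g11 <- gq$a * fr$i11 + gq$b * fr$i12   # wrt q1x
  g12 <- gq$a * fr$i21 + gq$b * fr$i22   # wrt q2x
  g21 <- gq$c * fr$i11 + gq$d * fr$i12   # wrt q1y
  g22 <- gq$c * fr$i21 + gq$d * fr$i22   # wrt q2y
  idx <- c(F[, 2], F[, 3], F[, 1])
  gx <- c(g11, g12, -(g11 + g12))
  gy <- c(g21, g22, -(g21 + g22))
  rs <- rowsum(cbind(gx, gy), group = idx)
  grad <- matrix(0, n, 2L)
  grad[as.integer(rownames(rs)), ] <- rs
  grad
}

# cotangent Laplacian of the source mesh (PSD; Hessian of the Dirichlet form)
cotan_laplacian <- function(mesh, fr) {
  V <- mesh$V; F <- mesh$F
  n <- nrow(V)
  lens <- function(p, q) sqrt(rowSums((V[F[, p], , drop = FALSE] -
                                       V[F[, q], , drop = FALSE])^2))
  l12 <- lens(1L, 2L); l23 <- lens(2L, 3L); l31 <- lens(3L, 1L)
  A <- fr$area
  # cot of angle opposite each edge, from areas and side lengths
  cot_at <- function(lopp, lb, lc) (lb^2 + lc^2 - lopp^2) / (4 * A)
  c3 <- cot_at(l12, l23, l31)  # angle at vertex 3, opposite edge (1,2)
  c1 <- cot_at(l23, l31, l12)
  c2 <- cot_at(l31, l12, l23)
  ii <- c(F[, 1], F[, 2], F[, 3])
  jj <- c(F[, 2], F[, 3], F[, 1])
  ww <- c(c3, c1, c2) / 2
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(W)) - W
}

# largest admissible step before any triangle flips along direction dirv
flip_cap_step <- function(F, uv, dirv, fr, cap) {
  j0 <- jacobian_entries(F, uv, fr)
  jd <- jacobian_entries(F, dirv, fr)   # direction is linear in vertices
  c0 <- j0$a * j0$d - j0$b * j0$c
  c1 <- j0$a * jd$d + jd$a * j0$d - j0$b * jd$c - jd$b * j0$c
  c2 <- jd$a * jd$d - jd$b * jd$c
  amax <- Inf
  # smallest positive root of c2 t^2 + c1 t + c0 = 0 per triangle
  lin <- abs(c2) < 1e-300
  t_lin <- ifelse(lin & c1 < 0, -c0 / c1, Inf)
  disc <- c1^2 - 4 * c2 * c0
  has <- !lin & disc >= 0
  sq <- sqrt(pmax(disc, 0))
  r1 <- (-c1 - sq) / (2 * c2)
  r2 <- (-c1 + sq) / (2 * c2)
  pos_min <- function(r) ifelse(has & r > 0, r, Inf)
  tq <- pmin(pos_min(r1), pos_min(r2))
  amax <- min(t_lin, tq, na.rm = TRUE)
  cap * amax
}

#' Minimize flattening distortion under a flip barrier
#'
#' Starting from a locally injective embedding (normally [tutte_embed()]),
#' performs monotone descent of the configured barrier energy. Each
#' iteration solves for a preconditioned descent direction, caps the step
#' strictly below the smallest step at which any triangle determinant would
#' reach zero, and backtracks until the energy decreases. Accepted iterates
#' therefore always satisfy `det df_t > 0` for every triangle, and the
#' energy trace is non-increasing. The run is deterministic.
#'
#' @param mesh a [sm_trimesh].
#' @param init an `sm_embedding` with all `det df_t > 0`; an initialization
#'   containing an inverted triangle is rejected (this solver does not
#'   repair invalid maps).
#' @param cfg a [flatten_config()].
#' @return An `sm_embedding` with fields `uv`, `sigma1`, `sigma2`, `det`,
#'   `energy_trace` (iteration, energy, min_det per accepted iterate) and
#'   `converged`.
#' @export
minimize_distortion <- function(mesh, init, cfg = flatten_config()) {
  stopifnot(inherits(mesh, "sm_trimesh"), inherits(init, "sm_embedding"),
            inherits(cfg, "sm_flatten_config"))
  F <- mesh$F
  n <- nrow(mesh$V)
  fr <- triangle_frames(mesh)
  jj0 <- jacobian_entries(F, init$uv, fr)
  if (any(jj0$a * jj0$d - jj0$b * jj0$c <= 0)) {
    stop("initialization contains inverted triangles (det df_t <= 0); ",
         "this solver requires a locally injective start")
  }
  name <- cfg$optimized_energy

  fixed <- if (cfg$boundary == "fixed") boundary_loop(mesh) else integer(0)

  L <- cotan_laplacian(mesh, fr)
  eps <- 1e-8 * mean(Matrix::diag(L))
  K <- L + Matrix::Diagonal(n, eps)
  solveK <- if (cfg$preconditioner == "sobolev") {
    ch <- Matrix::Cholesky(methods::as(K, "symmetricMatrix"), LDL = FALSE)
    function(g) as.matrix(Matrix::solve(ch, g))
  } else {
    dk <- Matrix::diag(K)
    function(g) g / dk
  }

  uv <- init$uv
  jj <- jacobian_entries(F, uv, fr)
  E <- opt_energy_value(name, jj, fr$area)
  trace_it <- list(data.frame(iteration = 0L, energy = E,
                              min_det = min(jj$a * jj$d - jj$b * jj$c)))
  converged <- FALSE

  for (it in seq_len(cfg$max_iters)) {
    gq <- opt_energy_grad(name, jj, fr$area)
    grad <- scatter_gradient(F, n, gq, fr)
    if (length(fixed)) grad[fixed, ] <- 0
    if (max(abs(grad)) < cfg$grad_tolerance) { converged <- TRUE; break }

    dirv <- -solveK(grad)
    if (length(fixed)) dirv[fixed, ] <- 0
    if (sum(dirv * grad) >= 0) dirv <- -grad  # safeguard: fall back to steepest

    amax <- flip_cap_step(F, uv, dirv, fr, cfg$step_cap_factor)
    alpha <- min(1, amax)
    accepted <- FALSE
    while (alpha > 1e-16) {
      uv_try <- uv + alpha * dirv
      jj_try <- jacobian_entries(F, uv_try, fr)
      E_try <- opt_energy_value(name, jj_try, fr$area)
      if (is.finite(E_try) && E_try < E) { accepted <- TRUE; break }
      alpha <- alpha * cfg$line_search_shrink
    }
    if (!accepted) { converged <- TRUE; break }  # no admissible decrease left

    rel_dec <- (E - E_try) / max(abs(E), 1e-300)
    uv <- uv_try; jj <- jj_try; E <- E_try
    trace_it[[length(trace_it) + 1L]] <-
      data.frame(iteration = it, energy = E,
                 min_det = min(jj$a * jj$d - jj$b * jj$c))
    if (rel_dec < cfg$energy_tolerance) { converged <- TRUE; break }
  }

  new_embedding(mesh, uv, do.call(rbind, trace_it), config = cfg,
                converged = converged)
}

#' Flatten a mesh end to end
#'
#' Convenience wrapper: Tutte initialization followed by
#' [minimize_distortion()].
#'
#' @param mesh a disk-topology [sm_trimesh].
#' @param cfg a [flatten_config()].
#' @return An `sm_embedding`.
#' @export
flatten_mesh <- function(mesh, cfg = flatten_config()) {
  init <- tutte_embed(mesh, weights = cfg$weights)
  minimize_distortion(mesh, init, cfg)
}
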