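# shared fixtures and independent oracles

flat_surface <- function(N = 8, z = 0) {
  g <- seq(0, 1, length.out = N)
  sm_surface(g, g, matrix(z, N, N))
}

bump_surface <- function(N = 8, amplitude = 0.3) {
  g <- seq(0, 1, length.out = N)
  z <- amplitude * outer(g, g, function(x, y) {
    exp(-((x - 0.5)^2 + (y - 0.5)^2) / 0.05)
  })
  sm_surface(g, g, z)
}

# independent Jacobian oracle: explicit frame construction + R's svd()
oracle_jacobian <- function(p0, p1, p2, q0, q1, q2) {
  e1 <- p1 - p0; e2 <- p2 - p0
  a1 <- e1 / sqrt(sum(e1^2))
  nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  a2 <- c(nrm[2] * a1[3] - nrm[3] * a1[2],
          nrm[3] * a1[1] - nrm[1] * a1[3],
          nrm[1] * a1[2] - nrm[2] * a1[1])
  P <- cbind(c(sum(e1 * a1), sum(e1 * a2)), c(sum(e2 * a1), sum(e2 * a2)))
  Q <- cbind(q1 - q0, q2 - q0)
  J <- Q %*% solve(P)
  d <- svd(J)$d
  s2 <- if (det(J) < 0) -d[2] else d[2]
  list(J = J, s1 = d[1], s2 = s2)
}

# a random uniformly-rotated 3x3 rotation matrix
random_rotation <- function() {
  M <- matrix(rnorm(9), 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# one-triangle mesh in 3D with its exact isometric planar unfolding
unfolded_triangle <- function(p0, p1, p2) {
  mesh <- sm_trimesh(rbind(p0, p1, p2), matrix(1:3, 1))
  e1 <- p1 - p0; e2 <- p2 - p0
  l1 <- sqrt(sum(e1^2))
  x2 <- sum(e1 * e2) / l1
  y2 <- sqrt(sum(e2^2) - x2^2)
  uv <- rbind(c(0, 0), c(l1, 0), c(x2, y2))
  list(mesh = mesh, uv = uv)
}

make_table <- function(n_per_class = 30, n_groups = 10, p = 5, sep = 3,
                       classes = c("a", "b"), seed = 1) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  cls <- rep(classes, each = n_per_class)
  labels <- data.frame(
    id = sprintf("r%03d", seq_len(n)),
    group = paste0(cls, "_g",
                   rep(rep(seq_len(n_groups), length.out = n_per_class),
                       length(classes))),
    class = cls)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  shift <- seq(-sep, sep, length.out = length(classes))
  X[, 1] <- X[, 1] + shift[match(cls, classes)]
  feature_table(labels, X)
}

expected_flat_signature <- function() {
  vals <- c(arap = 0, symmetric_dirichlet = 1, qi = 1, qc = 1, mips = 2,
            ad = 1, dirichlet = 1, cf = 1)
  out <- rep(vals, each = 2)
  names(out) <- signature_feature_names()
  out
}
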