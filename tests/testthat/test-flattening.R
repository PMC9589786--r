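test_that("Tutte with uniform weights places a lone interior vertex at the
           neighbour mean", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0.5, 0.5, 0.2))
  F <- rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5))
  mesh <- sm_trimesh(V, F)
  emb <- tutte_embed(mesh, weights = "uniform")
  expect_equal(emb$uv[5, ], colMeans(emb$uv[1:4, ]), tolerance = 1e-10)
  # equal boundary edge lengths: vertices at quarter turns of the circle,
  # so the interior vertex sits at the origin
  expect_equal(emb$uv[5, ], c(0, 0), tolerance = 1e-10)
  expect_true(all(emb$det > 0))
})

test_that("Tutte on the 2x2 mesh is pure boundary placement", {
  emb <- tutte_embed(build_mesh(flat_surface(2)))
  expect_equal(sqrt(rowSums(emb$uv^2)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(emb$det > 0))
})

test_that("Tutte initialization is flip-free on random height fields", {
  for (s in 1:10) {
    mesh <- generate_height_field_mesh("random", N = 12, amplitude = 0.4,
                                       seed = s)
    for (w in c("mean_value", "uniform")) {
      emb <- tutte_embed(mesh, weights = w)
      expect_true(all(emb$det > 0))
    }
  }
})

test_that("flat surfaces flatten to an isometry", {
  mesh <- build_mesh(flat_surface(8))
  emb <- flatten_mesh(mesh)
  expect_lt(max(abs(emb$sigma1 - 1)), 1e-6)
  expect_lt(max(abs(emb$sigma2 - 1)), 1e-6)
  sd_glob <- global_distortion(
    evaluate_energy("symmetric_dirichlet", emb$sigma1, emb$sigma2),
    triangle_areas(mesh))
  expect_equal(sd_glob, 1, tolerance = 1e-9)
})

test_that("descent is monotone and never exceeds the Tutte energy", {
  for (s in 1:3) {
    mesh <- generate_height_field_mesh("gaussian_bumps", N = 10,
                                       amplitude = 0.4, seed = s)
    init <- tutte_embed(mesh)
    emb <- minimize_distortion(mesh, init,
                               flatten_config(max_iters = 50))
    tr <- emb$energy_trace
    expect_true(all(diff(tr$energy) <= 0))
    expect_lte(tail(tr$energy, 1), init$energy_trace$energy[1])
    expect_true(all(tr$min_det > 0))
  }
})

test_that("an isometric unfolding is recognized as already optimal", {
  u <- unfolded_triangle(c(0, 0, 0), c(1, 0.2, 0.4), c(0.1, 1.1, -0.3))
  tj <- triangle_jacobians(u$mesh, u$uv)
  expect_equal(tj$sigma1, 1, tolerance = 1e-12)
  expect_equal(tj$sigma2, 1, tolerance = 1e-12)
  init <- spectromesh:::new_embedding(u$mesh, u$uv, energy_trace = NULL)
  emb <- minimize_distortion(u$mesh, init, flatten_config())
  # gradient vanishes at the isometry: no iterations accepted
  expect_equal(max(emb$energy_trace$iteration), 0L)
  expect_equal(emb$uv, u$uv, tolerance = 1e-12)
})

test_that("Jacobians match the brute-force SVD oracle", {
  set.seed(11)
  for (k in 1:50) {
    p0 <- rnorm(3); p1 <- rnorm(3); p2 <- rnorm(3)
    q0 <- rnorm(2); q1 <- rnorm(2); q2 <- rnorm(2)
    mesh <- sm_trimesh(rbind(p0, p1, p2), matrix(1:3, 1))
    tj <- triangle_jacobians(mesh, rbind(q0, q1, q2))
    or <- oracle_jacobian(p0, p1, p2, q0, q1, q2)
    expect_equal(tj$sigma1, or$s1, tolerance = 1e-10)
    expect_equal(tj$sigma2, or$s2, tolerance = 1e-10)
  }
})

test_that("simple maps have the expected singular values", {
  # identity map of a planar triangle
  tri <- sm_trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.3, 0.8, 0)),
                    matrix(1:3, 1))
  uv_id <- tri$V[, 1:2]
  tj <- triangle_jacobians(tri, uv_id)
  expect_equal(c(tj$sigma1, tj$sigma2), c(1, 1), tolerance = 1e-12)
  expect_equal(as.vector(tj$J), c(1, 0, 0, 1), tolerance = 1e-12)
  # uniform 2x scaling
  tj2 <- triangle_jacobians(tri, 2 * uv_id)
  expect_equal(c(tj2$sigma1, tj2$sigma2), c(2, 2), tolerance = 1e-12)
  # reflection flips the sign of sigma2
  refl <- uv_id %*% diag(c(-1, 1))
  tjr <- triangle_jacobians(tri, refl)
  expect_lt(tjr$sigma2, 0)
  expect_lt(tjr$det, 0)
})

test_that("singular values are invariant to rigid motions of the source", {
  set.seed(12)
  mesh <- generate_height_field_mesh("gaussian_bumps", N = 6,
                                     amplitude = 0.5, seed = 2)
  uv <- tutte_embed(mesh)$uv
  base <- triangle_jacobians(mesh, uv)
  for (k in 1:5) {
    R <- random_rotation()
    shift <- rnorm(3)
    rot <- sm_trimesh(mesh$V %*% t(R) +
                        matrix(shift, nrow(mesh$V), 3, byrow = TRUE),
                      mesh$F)
    tj <- triangle_jacobians(rot, uv)
    expect_equal(tj$sigma1, base$sigma1, tolerance = 1e-10)
    expect_equal(tj$sigma2, base$sigma2, tolerance = 1e-10)
  }
})

test_that("degenerate and invalid inputs are rejected", {
  degen <- sm_trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                      matrix(1:3, 1))
  expect_error(triangle_jacobians(degen, degen$V[, 1:2]), "degenerate")
  mesh <- build_mesh(flat_surface(3))
  emb <- tutte_embed(mesh)
  flipped <- emb
  flipped$uv[, 1] <- -flipped$uv[, 1]  # global reflection inverts all
  expect_error(minimize_distortion(mesh, flipped), "inverted")
  expect_error(flatten_config(optimized_energy = "dirichlet"),
               "non-barrier|unknown")
  expect_error(triangle_jacobians(mesh, emb$uv[-1, ]), "n x 2")
})

test_that("analytic energy gradient matches finite differences", {
  set.seed(13)
  mesh <- generate_height_field_mesh("random", N = 4, amplitude = 0.3,
                                     seed = 5)
  uv <- tutte_embed(mesh)$uv
  fr <- spectromesh:::triangle_frames(mesh)
  for (name in c("symmetric_dirichlet", "mips")) {
    jj <- spectromesh:::jacobian_entries(mesh$F, uv, fr)
    gq <- spectromesh:::opt_energy_grad(name, jj, fr$area)
    grad <- spectromesh:::scatter_gradient(mesh$F, nrow(mesh$V), gq, fr)
    ener <- function(u) {
      spectromesh:::opt_energy_value(
        name, spectromesh:::jacobian_entries(mesh$F, u, fr), fr$area)
    }
    h <- 1e-6
    for (probe in list(c(6, 1), c(11, 2), c(1, 1))) {
      up <- uv; up[probe[1], probe[2]] <- up[probe[1], probe[2]] + h
      dn <- uv; dn[probe[1], probe[2]] <- dn[probe[1], probe[2]] - h
      fd <- (ener(up) - ener(dn)) / (2 * h)
      expect_equal(grad[probe[1], probe[2]], fd, tolerance = 1e-5)
    }
  }
})

test_that("flattening is deterministic", {
  mesh <- generate_height_field_mesh("random", N = 8, amplitude = 0.3,
                                     seed = 3)
  cfg <- flatten_config(max_iters = 30)
  e1 <- flatten_mesh(mesh, cfg)
  e2 <- flatten_mesh(mesh, cfg)
  expect_identical(e1$uv, e2$uv)
  expect_identical(e1$energy_trace$energy, e2$energy_trace$energy)
})
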