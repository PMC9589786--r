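test_that("energy formulas reproduce hand-computed values", {
  # rigid map: every energy at its minimum
  at11 <- vapply(names(energy_registry),
                 function(nm) evaluate_energy(nm, 1, 1), numeric(1))
  expect_equal(at11, c(arap = 0, symmetric_dirichlet = 1, qi = 1, qc = 1,
                       mips = 2, ad = 1, dirichlet = 1, cf = 1))
  # (2, 1)
  expect_equal(evaluate_energy("arap", 2, 1), 9)
  expect_equal(evaluate_energy("symmetric_dirichlet", 2, 1), 1.5625)
  expect_equal(evaluate_energy("qi", 2, 1), 2)
  expect_equal(evaluate_energy("qc", 2, 1), 2)
  expect_equal(evaluate_energy("mips", 2, 1), 2.5)
  expect_equal(evaluate_energy("ad", 2, 1), 2)
  expect_equal(evaluate_energy("dirichlet", 2, 1), 2.5)
  expect_equal(evaluate_energy("cf", 2, 1), 1.5)
  # (2, 0.5): area-preserving but non-conformal
  expect_equal(evaluate_energy("ad", 2, 0.5), 1)
  expect_equal(evaluate_energy("qi", 2, 0.5), 2)
  # conformal maps: qc = 1, mips = 2 at any sigma1 = sigma2
  for (s in c(0.3, 1, 2.7)) {
    expect_equal(evaluate_energy("qc", s, s), 1)
    expect_equal(evaluate_energy("mips", s, s), 2)
  }
})

test_that("qc dilatation is symmetric in its arguments", {
  set.seed(21)
  a <- runif(50, 0.1, 5); b <- runif(50, 0.1, 5)
  f <- energy_registry$qc
  expect_equal(f(a, b), f(b, a), tolerance = 1e-14)
})

test_that("energy lower bounds hold on random singular-value pairs", {
  set.seed(22)
  s2 <- exp(runif(2000, -2, 2))
  s1 <- s2 * exp(runif(2000, 0, 2))  # s1 >= s2 > 0
  expect_true(all(evaluate_energy("arap", s1, s2) >= 0))
  expect_true(all(evaluate_energy("symmetric_dirichlet", s1, s2) >= 1))
  expect_true(all(evaluate_energy("qi", s1, s2) >= 1))
  expect_true(all(evaluate_energy("qc", s1, s2) >= 1))
  expect_true(all(evaluate_energy("mips", s1, s2) >= 2))
  expect_true(all(evaluate_energy("ad", s1, s2) >= 1))
  expect_true(all(evaluate_energy("dirichlet", s1, s2) > 0))
  expect_true(all(evaluate_energy("cf", s1, s2) > 0))
})

test_that("invalid energy inputs are rejected", {
  expect_error(evaluate_energy("nope", 1, 1), "unknown energy")
  expect_error(evaluate_energy("arap", 1, -0.5), "invalid")
  expect_error(evaluate_energy("arap", 0.5, 1), "sigma1")
})

test_that("median split follows the strict-below / at-or-above convention", {
  mk <- function(fcg) {
    # build a mesh whose triangles have the prescribed centroid frequencies
    n <- length(fcg)
    V <- do.call(rbind, lapply(seq_len(n), function(i) {
      rbind(c(0, fcg[i], 0), c(1, fcg[i], 0), c(0.5, fcg[i], 1))
    }))
    F <- matrix(seq_len(3 * n), ncol = 3, byrow = TRUE)
    sm_trimesh(V, F)
  }
  # even count: median between the two middle values
  sp <- split_by_frequency(mk(c(1, 2, 3, 4)))
  expect_equal(sp$median_f, 2.5)
  expect_equal(sp$band1, c(1L, 2L))
  expect_equal(sp$band2, c(3L, 4L))
  # odd count: the median triangle itself goes to the upper band
  sp <- split_by_frequency(mk(c(1, 2, 3)))
  expect_equal(sp$median_f, 2)
  expect_equal(sp$band1, 1L)
  expect_equal(sp$band2, c(2L, 3L))
  # ties at the median go up
  sp <- split_by_frequency(mk(c(1, 2, 2, 4)))
  expect_equal(sp$band1, 1L)
  expect_equal(sp$band2, c(2L, 3L, 4L))
  # constant frequencies: lower band empty
  sp <- split_by_frequency(mk(c(2, 2, 2)))
  expect_length(sp$band1, 0L)
  expect_equal(sp$band2, 1:3)
})

test_that("band partition is conservative on real meshes", {
  for (s in 1:5) {
    mesh <- generate_height_field_mesh("random", N = 7, seed = s)
    sp <- split_by_frequency(mesh)
    m <- nrow(mesh$F)
    expect_equal(sort(c(sp$band1, sp$band2)), seq_len(m))
    expect_length(intersect(sp$band1, sp$band2), 0L)
  }
})

test_that("global distortion equals the naive loop and is sandwiched", {
  # hand values
  expect_equal(global_distortion(c(1, 3), c(1, 1)), 2)
  expect_equal(global_distortion(c(1, 3), c(1, 3)), 2.5)
  expect_equal(global_distortion(rep(4.2, 7), runif(7, 0.1, 1)), 4.2)
  # naive-summation oracle and the weighted-mean sandwich
  set.seed(23)
  for (k in 1:20) {
    n <- sample(2:30, 1)
    ev <- runif(n, 0, 10); ar <- runif(n, 0.01, 2)
    sub <- sort(sample(n, sample(n, 1)))
    naive <- 0; tot <- 0
    for (t in sub) { naive <- naive + ev[t] * ar[t]; tot <- tot + ar[t] }
    got <- global_distortion(ev, ar, sub)
    expect_equal(got, naive / tot, tolerance = 1e-12)
    expect_gte(got, min(ev[sub]) - 1e-12)
    expect_lte(got, max(ev[sub]) + 1e-12)
  }
  expect_warning(g <- global_distortion(1:3, rep(1, 3), integer(0)), "empty")
  expect_true(is.na(g))
})

test_that("flat surfaces yield the all-minima signature", {
  mesh <- build_mesh(flat_surface(8))
  emb <- flatten_mesh(mesh)
  sig <- extract_signature(mesh, emb)
  expect_equal(unclass(sig), expected_flat_signature(), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_named(sig, signature_feature_names())
})

test_that("signature bands respect every energy's lower bound", {
  mesh <- generate_height_field_mesh("gaussian_bumps", N = 10,
                                     amplitude = 0.5, seed = 4)
  emb <- flatten_mesh(mesh, flatten_config(max_iters = 40))
  sig <- extract_signature(mesh, emb)
  lb <- rep(c(arap = 0, symmetric_dirichlet = 1, qi = 1, qc = 1, mips = 2,
              ad = 1, dirichlet = 0, cf = 0), each = 2)
  expect_true(all(sig >= lb - 1e-9))
})

test_that("steeper bumps mean more isometric distortion", {
  sd_full <- function(amplitude, s) {
    mesh <- generate_height_field_mesh("gaussian_bumps", N = 10,
                                       amplitude = amplitude, seed = s)
    emb <- flatten_mesh(mesh, flatten_config(max_iters = 40))
    global_distortion(
      evaluate_energy("symmetric_dirichlet", emb$sigma1, emb$sigma2),
      triangle_areas(mesh))
  }
  lo <- vapply(1:6, function(s) sd_full(0.15, s), numeric(1))
  hi <- vapply(1:6, function(s) sd_full(0.45, s), numeric(1))
  expect_true(all(hi >= lo))
})

test_that("constant-frequency meshes fall back to full-mesh bands", {
  V <- rbind(c(0, 0.5, 0), c(1, 0.5, 0), c(0.5, 0.5, 1),
             c(1.5, 0.5, 1))
  mesh <- sm_trimesh(V, rbind(c(1, 2, 3), c(2, 4, 3)))
  emb <- tutte_embed(mesh, weights = "uniform")
  expect_warning(sig <- extract_signature(mesh, emb), "constant")
  expect_length(sig, 16L)
  expect_true(all(is.finite(sig)))
  # both bands equal the full-mesh value
  expect_equal(sig[seq(1, 15, by = 2)], sig[seq(2, 16, by = 2)],
               ignore_attr = TRUE)
})
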