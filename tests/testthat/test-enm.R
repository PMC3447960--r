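random_model <- function(n, seed, spread = 1.0) {
  set.seed(seed)
  as_particle_model(tibble::tibble(
    chain = "A", resid = seq_len(n), domain = "d",
    x = runif(n, 0, spread), y = runif(n, 0, spread), z = runif(n, 0, spread)
  ))
}

test_that("Kirchhoff matrix has the Laplacian closed forms and matches the oracle", {
  two <- matrix(c(0, 0, 0, 0.5, 0, 0), 2, 3, byrow = TRUE)
  K <- build_kirchhoff(two, cutoff = 0.7)
  expect_equal(K, matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(sort(eigen(K)$values), c(0, 2))

  for (seed in 1:5) {
    m <- as.matrix(random_model(20, seed)[, c("x", "y", "z")])
    K <- build_kirchhoff(m, cutoff = 0.4)
    expect_equal(K, oracle_kirchhoff(m, 0.4))
    expect_true(all(rowSums(K) == 0))
  }

  dup <- rbind(two, two[1, ])
  expect_warning(build_kirchhoff(dup, 0.7), "coincident")
})

test_that("Hessian matches the 1-D spring closed form, the oracle, and kills rigid motions", {
  two <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  H <- build_hessian(two, cutoff = 1.3)
  nonzero <- which(H != 0, arr.ind = TRUE)
  expect_true(all(nonzero %% 3 == 1))  # x-x positions only
  ev <- sort(eigen(H, symmetric = TRUE)$values)
  expect_equal(ev, c(rep(0, 5), 2), tolerance = 1e-12)

  for (seed in 1:3) {
    m <- as.matrix(random_model(15, seed)[, c("x", "y", "z")])
    expect_equal(build_hessian(m, 0.8), oracle_hessian(m, 0.8),
                 tolerance = 1e-12)
  }

  m <- as.matrix(random_model(10, 4)[, c("x", "y", "z")])
  H <- build_hessian(m, cutoff = 2.0)
  # rigid-body basis: 3 translations + 3 infinitesimal rotations
  rigid <- cbind(
    rep(c(1, 0, 0), 10), rep(c(0, 1, 0), 10), rep(c(0, 0, 1), 10),
    as.numeric(t(cbind(0, -m[, 3], m[, 2]))),
    as.numeric(t(cbind(m[, 3], 0, -m[, 1]))),
    as.numeric(t(cbind(-m[, 2], m[, 1], 0)))
  )
  expect_lt(max(abs(H %*% rigid)), 1e-8)

  expect_error(build_hessian(rbind(m, m[1, ]), 2.0), "oincident")
})

test_that("decompose_modes identifies zero modes and reconstructs the input", {
  m <- as.matrix(random_model(25, 6, spread = 0.8)[, c("x", "y", "z")])
  K <- build_kirchhoff(m, cutoff = 0.6)
  modes <- decompose_modes(K, "gnm", 0.6)
  comps <- rodbend:::graph_components(K)
  expect_equal(modes$n_zero, length(unique(comps)))

  recon <- modes$vectors %*% (modes$values * t(modes$vectors))
  expect_lt(max(abs(recon - K)), 1e-7)
  expect_lt(max(abs(crossprod(modes$vectors) - diag(nrow(K)))), 1e-8)

  expect_error(decompose_modes(matrix(1:9, 3, 3)), "symmetric")
})

test_that("a symmetric dumbbell puts the slow-mode hinge in the linker", {
  blob <- function(center) {
    g <- expand.grid(x = c(0, 0.4, 0.8), y = c(0, 0.4), z = c(0, 0.4))[1:10, ]
    sweep(as.matrix(g), 2, center, "+")
  }
  linker <- cbind(seq(1.2, 2.8, by = 0.4), 0.2, 0.2)
  coords <- rbind(blob(c(0, 0, 0)), linker, blob(c(3.2, 0, 0)))
  model <- as_particle_model(tibble::tibble(
    chain = "A", resid = seq_len(nrow(coords)), domain = "d",
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  ))
  g <- gnm(model, cutoff = 0.7)
  expect_equal(g$n_zero, 1)  # connected
  runs <- slow_mode_hinges(g, threshold_quantile = 0.25)
  linker_ids <- 11:15
  expect_true(any(attr(runs, "residues") %in% linker_ids))
  # the deepest run (global minimum-magnitude residue) sits at the linker centre
  mag <- attr(runs, "magnitudes")
  deepest <- runs[which.min(mag$mag[match(runs$resid_min, mag$resid)]), ]
  expect_true(deepest$resid_min %in% 12:14)
  expect_true(deepest$resid_start >= 10 && deepest$resid_end <= 16)

  expect_length(attr(slow_mode_hinges(g, threshold_quantile = 0), "residues"),
                0)
})

test_that("GNM slow-mode hinge on the bent dimer overlaps the bisection hinge", {
  for (seed in 1:5) {
    base <- build_rod(rod_spec(noise_sd = 0.05, seed = seed))
    bent <- bend_at_hinge(base, 268, 30, axis_seed = seed)
    g <- gnm(bent, cutoff = 0.7)
    runs <- suppressWarnings(slow_mode_hinges(g, threshold_quantile = 0.1))
    gnm_set <- attr(runs, "residues")
    prof_hinge <- attr(bisection_msd_profile(bent), "hinge")
    expect_true(any(abs(gnm_set - prof_hinge) <= 5))
  }
})

test_that("straight-rod ANM has 6 zero modes and a degenerate transverse bending pair", {
  rod3 <- build_rod(rod_spec(n_residues_per_chain = 100, n_chains = 3,
                             hinge_residue = 50, noise_sd = 0))
  a <- anm(rod3, cutoff = 1.3)
  expect_equal(a$n_zero, 6)
  nz <- a$values[abs(a$values) >= a$tol]
  expect_lt(abs(nz[2] / nz[1] - 1), 0.05)
  # the pair is transverse: x/y displacement dominates z
  v <- matrix(a$vectors[, a$n_zero + 1], ncol = 3, byrow = TRUE)
  expect_gt(sum(v[, 1:2]^2), 10 * sum(v[, 3]^2))
})

test_that("GNM fluctuation profile is invariant to rigid transformation", {
  model <- random_model(40, 8, spread = 1.2)
  m <- as.matrix(model[, c("x", "y", "z")])
  R <- rodbend:::rotation_matrix(c(1, 2, -1), 77)
  moved <- model
  moved[, c("x", "y", "z")] <- as.data.frame(sweep(m %*% t(R), 2, c(5, 1, -3), "+"))
  msf1 <- gnm_msf(gnm(model, cutoff = 0.8))
  msf2 <- gnm_msf(gnm(moved, cutoff = 0.8))
  expect_equal(msf1, msf2, tolerance = 1e-8)
})
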