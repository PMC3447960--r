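test_that("superpose recovers exact rigid transforms and matches the grid oracle", {
  set.seed(11)
  P <- matrix(rnorm(30), 10, 3)
  s <- superpose(P, P)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)

  R <- rodbend:::rotation_matrix(c(3, 1, -2), 51)
  Q <- P %*% t(R) + matrix(rep(c(1, -4, 2), each = 10), 10, 3)
  expect_lt(superpose(P, Q)$rmsd, 1e-9)

  for (seed in 1:3) {
    set.seed(seed)
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    opt <- superpose(A, B)$rmsd
    grid <- oracle_rmsd_grid(A, B)
    rmax <- sqrt(max(rowSums(sweep(A, 2, colMeans(A))^2)))
    delta <- sqrt(4 * pi / 10000) + 2 * pi / 180
    expect_gte(grid, opt - 1e-9)       # grid cannot beat the optimum
    expect_lte(grid - opt, rmax * delta)
  }

  expect_error(superpose(P[1:2, ], P[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "rank")
})

test_that("rmsd_series is zero for identical frames and matches Gaussian expectations", {
  topo <- tibble::tibble(chain = "A", resid = 1:50, domain = "d")
  set.seed(12)
  base <- matrix(rnorm(150, sd = 1), 50, 3)
  ens_same <- new_ensemble(topo, replicate(5, base, simplify = FALSE))
  rs <- rmsd_series(ens_same)
  expect_true(all(rs$rmsd < 1e-12))
  expect_equal(attr(rs, "modal"), 0.01)  # midpoint of the first 0.02 nm bin

  # frames = reference + isotropic noise: post-fit mean RMSD ~ sqrt(3) sd
  sdn <- 0.1
  frames <- c(list(base), lapply(1:40, function(i) {
    base + matrix(rnorm(150, sd = sdn), 50, 3)
  }))
  rs2 <- rmsd_series(new_ensemble(topo, frames), reference = 1)
  expect_lt(abs(mean(rs2$rmsd[-1]) - sqrt(3) * sdn) / (sqrt(3) * sdn), 0.10)

  expect_error(rmsd_series(ens_same, reference = 99), "reference")
})

test_that("domain-local superposition hides rigid hinge bending", {
  base <- build_rod(rod_spec(n_residues_per_chain = 200, hinge_residue = 100,
                             noise_sd = 0))
  frames <- lapply(c(0, 60), function(a) {
    bent <- bend_at_hinge(base, 100, a, axis = c(0, 1, 0))
    as.matrix(bent[, c("x", "y", "z")])
  })
  ens <- new_ensemble(base[, c("chain", "resid", "domain")], frames)
  rs <- rmsd_series(ens, selection = "resid 110:200", reference = 1)
  expect_lt(rs$rmsd[2], 1e-9)
})

test_that("GROMOS clustering separates constructed groups and matches the oracle", {
  topo <- tibble::tibble(chain = "A", resid = 1:30, domain = "d")
  set.seed(13)
  centres <- list(matrix(rnorm(90), 30, 3),
                  matrix(rnorm(90) + 4, 30, 3),
                  matrix(rnorm(90) - 4, 30, 3))
  frames <- unlist(lapply(seq_along(centres), function(g) {
    lapply(1:4, function(i) centres[[g]] + matrix(rnorm(90, sd = 0.01), 30, 3))
  }), recursive = FALSE)
  ens <- new_ensemble(topo, frames)
  cl <- gromos_cluster(ens, cutoff = 0.3)
  expect_equal(nrow(cl$clusters), 3)
  expect_equal(sum(cl$clusters$size), 12)
  grp <- rep(1:3, each = 4)
  expect_true(all(tapply(cl$membership$cluster, grp,
                         function(v) length(unique(v))) == 1))

  orc <- oracle_gromos(cl$rmsd, 0.3)
  expect_equal(length(orc), nrow(cl$clusters))
  for (k in seq_along(orc)) {
    expect_equal(sort(cl$membership$frame[cl$membership$cluster == k]),
                 orc[[k]]$members)
    expect_equal(cl$clusters$centroid[k], orc[[k]]$centroid)
  }

  one <- new_ensemble(topo, replicate(4, centres[[1]], simplify = FALSE))
  c1 <- gromos_cluster(one, cutoff = 0.1)
  expect_equal(nrow(c1$clusters), 1)
  expect_equal(c1$clusters$centroid, 1)

  expect_error(gromos_cluster(ens, cutoff = 0), "cutoff")
})

test_that("cluster sizes are non-increasing and windows restrict the frames", {
  topo <- tibble::tibble(chain = "A", resid = 1:20, domain = "d")
  set.seed(14)
  frames <- lapply(1:15, function(i) matrix(rnorm(60, sd = 1), 20, 3))
  ens <- new_ensemble(topo, frames)
  cl <- gromos_cluster(ens, cutoff = 1.2)
  expect_true(all(diff(cl$clusters$size) <= 0))

  wcl <- gromos_cluster(ens, cutoff = 1.2, window = c(10, 14))
  expect_true(all(wcl$membership$frame %in% 11:15))
  expect_equal(sum(wcl$clusters$size), 5)
})

test_that("the representative is the RMSD medoid with deterministic ties", {
  # 3 frames on a line in conformation space: B is the middle structure
  topo <- tibble::tibble(chain = "A", resid = 1:10, domain = "d")
  set.seed(15)
  A <- matrix(rnorm(30), 10, 3)
  drift <- matrix(rnorm(30, sd = 0.3), 10, 3)
  frames <- list(A, A + drift, A + 2 * drift)
  ens <- new_ensemble(topo, frames)
  cl <- gromos_cluster(ens, cutoff = 10)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cluster_representative(cl), 2)

  # singleton cluster: its only member
  far <- new_ensemble(topo, list(A, A + 50))
  cf <- gromos_cluster(far, cutoff = 0.5)
  expect_equal(cf$clusters$representative, cf$clusters$centroid)

  # permuting frames relabels but preserves the partition
  perm <- c(3, 1, 2)
  ens_p <- new_ensemble(topo, frames[perm])
  cl_p <- gromos_cluster(ens_p, cutoff = 10)
  expect_equal(cl_p$clusters$size, cl$clusters$size)
  expect_equal(cluster_representative(cl_p), which(perm == 2))
})

test_that("pairwise RMSD matrices are symmetric with zero diagonal", {
  set.seed(16)
  frames <- lapply(1:6, function(i) matrix(rnorm(36), 12, 3))
  D <- rodbend:::pairwise_rmsd_matrix(frames)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D[upper.tri(D)] > 0))
})
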