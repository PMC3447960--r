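test_that("lipid counts reproduce the reference composition exactly", {
  counts <- allocate_counts(vesicle_spec())
  expect_equal(counts$total[counts$species == "DPPE"], 24500)
  expect_equal(counts$total[counts$species == "DPPG"], 7000)
  expect_equal(counts$total[counts$species == "CL"], 3500)
  expect_equal(sum(counts$total), 35000)
  expect_equal(counts$outer + counts$inner, counts$total)

  single <- allocate_counts(vesicle_spec(
    n_lipids_total = 1000, composition = c(DPPE = 1, DPPG = 0, CL = 0)))
  expect_equal(single$total, c(1000, 0, 0))

  # brute-force largest-remainder enumeration for total = 7
  fr <- c(a = 0.5, b = 0.3, c = 0.2)
  got <- rodbend:::largest_remainder(7, fr)
  exact <- 7 * fr
  expect_equal(sum(got), 7)
  expect_true(all(abs(got - exact) < 1))
  best <- NULL; best_err <- Inf
  for (i in 0:7) for (j in 0:(7 - i)) {
    k <- 7 - i - j
    err <- sum(abs(c(i, j, k) - exact))
    if (err < best_err) { best_err <- err; best <- c(i, j, k) }
  }
  expect_equal(sum(abs(got - exact)), best_err)

  expect_error(vesicle_spec(composition = c(DPPE = 0.5, DPPG = 0.2, CL = 0.2)),
               "sum to 1")
})

test_that("solve_radius closes the area equation and gives the ~70 nm vesicle", {
  spec <- vesicle_spec()
  r <- solve_radius(spec)
  expect_equal(round(2 * r$outer_radius / 10) * 10, 70)
  lhs <- 4 * pi * (r$outer_radius^2 + r$inner_radius^2)
  expect_equal(lhs, spec$n_lipids_total * spec$area_per_lipid,
               tolerance = 1e-6)

  odd <- vesicle_spec(n_lipids_total = 1234, area_per_lipid = 0.61,
                      bilayer_thickness = 3.1)
  ro <- solve_radius(odd)
  expect_equal(4 * pi * (ro$outer_radius^2 + ro$inner_radius^2),
               1234 * 0.61, tolerance = 1e-6)

  expect_error(vesicle_spec(n_lipids_total = 0), "positive")
  # too few lipids to close a vesicle around a 4 nm bilayer
  expect_error(solve_radius(vesicle_spec(n_lipids_total = 10)),
               "radius|inner")
})

test_that("place_lipids conserves counts, separation and leaflet radii deterministically", {
  spec <- vesicle_spec(n_lipids_total = 3000, seed = 42)
  v <- place_lipids(spec)
  counts <- allocate_counts(spec)
  got <- table(v$lipids$species)
  expect_equal(as.integer(got[counts$species]), counts$total)

  for (lf in c("outer", "inner")) {
    m <- as.matrix(v$lipids[v$lipids$leaflet == lf, c("x", "y", "z")])
    expect_equal(nrow(rodbend:::close_pairs(m, spec$min_separation)), 0)
    R <- if (lf == "outer") v$outer_radius else v$inner_radius
    expect_lt(max(abs(sqrt(rowSums(m^2)) - R)), 0.1)
  }

  v2 <- place_lipids(spec)
  expect_identical(v$lipids, v2$lipids)

  dense <- vesicle_spec(n_lipids_total = 3000, area_per_lipid = 0.05,
                        bilayer_thickness = 0.5, min_separation = 0.45)
  expect_error(place_lipids(dense), "cannot hold|min_separation")
})

test_that("protein sites are even, antipodal for two, and displace no species", {
  spec <- vesicle_spec(n_lipids_total = 2000, seed = 5)
  v <- place_lipids(spec)

  v2 <- place_proteins_evenly(v, 2)
  s <- as.matrix(v2$protein_sites[, c("x", "y", "z")])
  ang <- acos(sum(s[1, ] * s[2, ]) / sqrt(sum(s[1, ]^2) * sum(s[2, ]^2)))
  expect_gt(ang * 180 / pi, 179)

  v30 <- place_proteins_evenly(v, 30)
  s30 <- as.matrix(v30$protein_sites[, c("x", "y", "z")])
  u <- s30 / sqrt(rowSums(s30^2))
  cosang <- tcrossprod(u)
  min_sep <- min(acos(pmin(1, cosang[upper.tri(cosang)])))
  ideal <- sqrt(8 * pi / (sqrt(3) * 30))
  expect_gte(min_sep, 0.8 * ideal)

  v10 <- place_proteins_evenly(v, 10)
  expect_equal(table(v10$lipids$species), table(v$lipids$species))
  expect_equal(table(v30$lipids$species), table(v$lipids$species))

  # no lipid inside any footprint
  for (vv in list(v2, v30, v10)) {
    m <- as.matrix(vv$lipids[, c("x", "y", "z")])
    sm <- as.matrix(vv$protein_sites[, c("x", "y", "z")])
    for (k in seq_len(nrow(sm))) {
      d <- sqrt(colSums((t(m) - sm[k, ])^2))
      expect_gte(min(d), vv$protein_sites$footprint_radius[k])
    }
  }

  expect_error(place_proteins_evenly(v, 4, footprint_radius = 9), "half")
})

test_that("lipid Monte Carlo is deterministic, conservative and stays on-sphere", {
  spec <- vesicle_spec(n_lipids_total = 400, seed = 9)
  v <- place_proteins_evenly(place_lipids(spec), 2)
  am <- affinity_model(n_sweeps = 300, stride = 100, seed = 3)
  t1 <- run_lipid_dynamics(v, am)
  t2 <- run_lipid_dynamics(v, am)
  expect_identical(t1$frames, t2$frames)

  expect_identical(t1$lipids$species, v$lipids$species)
  for (f in t1$frames) {
    r <- sqrt(rowSums(f^2))
    expect_lt(max(abs(r - ifelse(t1$lipids$leaflet == "outer",
                                 v$outer_radius, v$inner_radius))), 1e-9)
    for (lf in c("outer", "inner")) {
      ml <- f[t1$lipids$leaflet == lf, ]
      expect_equal(nrow(rodbend:::close_pairs(ml, spec$min_separation)), 0)
    }
  }

  expect_error(run_lipid_dynamics(v, affinity_model(step_length = 0)), "step")
  expect_error(run_lipid_dynamics(place_lipids(spec), affinity_model()),
               "no protein sites")
})

test_that("flat energies leave the shell at bulk composition", {
  # with all well depths zero the uniform start is already the equilibrium
  # distribution, so every frame samples the null and can be pooled
  spec <- vesicle_spec(n_lipids_total = 4000, seed = 17)
  v <- place_proteins_evenly(place_lipids(spec), 40)
  am <- affinity_model(epsilon = c(CL = 0, DPPG = 0, DPPE = 0),
                       n_sweeps = 4000, stride = 100, seed = 5)
  traj <- run_lipid_dynamics(v, am)
  s <- enrichment_summary(shell_enrichment(traj), window = 1)
  expect_true(all(abs(s$enrich_bulk - 1) <= 0.1))
})

test_that("the dilute limit reproduces the Boltzmann factor", {
  spec <- vesicle_spec(n_lipids_total = 2000,
                       composition = c(DPPE = 0.95, DPPG = 0.03, CL = 0.02),
                       min_separation = 0.05, seed = 23)
  v <- place_proteins_evenly(place_lipids(spec), 12, footprint_radius = 0.05)
  am <- affinity_model(epsilon = c(CL = log(2), DPPG = 0, DPPE = 0),
                       n_sweeps = 8000, stride = 100, seed = 7)
  traj <- run_lipid_dynamics(v, am)
  s <- enrichment_summary(shell_enrichment(traj))
  expect_equal(s$enrich_bulk[s$species == "CL"], 2, tolerance = 0.2)
})

test_that("a protein-free vesicle stays well mixed through dynamics", {
  spec <- vesicle_spec(n_lipids_total = 2000, seed = 31)
  v <- place_lipids(spec)
  am <- affinity_model(epsilon = c(CL = 0, DPPG = 0, DPPE = 0),
                       n_sweeps = 2000, stride = 500, seed = 9)
  traj <- run_lipid_dynamics(v, am)
  for (f in seq_along(traj$frames)) {
    mx <- mixing_statistic(trajectory_frame(traj, f))
    expect_true(all(abs(mx$demixing_index) < 0.05))
  }
})
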