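test_that("PDB and GRO round trips preserve labels and coordinates", {
  rod <- build_rod(rod_spec(n_residues_per_chain = 40, hinge_residue = 20,
                            noise_sd = 0.03, seed = 2))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(rod, pdb)
  rt <- read_structure(pdb, domain_map = attr(rod, "domain_map"))
  expect_identical(rt$chain, rod$chain)
  expect_identical(rt$resid, rod$resid)
  # PDB precision: 0.001 A = 0.0001 nm
  expect_lt(max(abs(as.matrix(rt[, c("x", "y", "z")]) -
                      as.matrix(rod[, c("x", "y", "z")]))), 1e-4)

  gro <- withr::local_tempfile(fileext = ".gro")
  write_structure(rod, gro)
  rg <- read_structure(gro)
  expect_identical(rg$chain, rod$chain)  # chains inferred from resid resets
  expect_lt(max(abs(as.matrix(rg[, c("x", "y", "z")]) -
                      as.matrix(rod[, c("x", "y", "z")]))), 5e-4 + 1e-12)
})

test_that("a handcrafted 3-atom PDB parses to exact nm coordinates", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1      10.000  20.000  30.000  1.00  0.00",
    "ATOM      2  CA  GLY A   2      11.500  20.000  30.000  1.00  0.00",
    "ATOM      3  CA  GLY B   1       0.250  -1.000   2.750  1.00  0.00",
    "END"
  ), pdb)
  m <- read_structure(pdb)
  expect_equal(m$x, c(1.0, 1.15, 0.025))
  expect_equal(m$y, c(2.0, 2.0, -0.1))
  expect_equal(m$z, c(3.0, 3.0, 0.275))
  expect_equal(m$chain, c("A", "A", "B"))
  expect_equal(m$resid, c(1L, 2L, 1L))
})

test_that("GRO headers must match the body and malformed records are located", {
  gro <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("title", "    3",
               "    1DPPE     P    1   1.000   2.000   3.000",
               "    2DPPE     P    2   1.500   2.000   3.000",
               "  10.0  10.0  10.0"), gro)
  expect_error(read_structure(gro), "3 atom lines promised")

  bad <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("title", "    2",
               "    1DPPE     P    1   1.000   2.000   3.000",
               "    2DPPE     P    2   xxxxx   2.000   3.000",
               "  10.0  10.0  10.0"), bad)
  expect_error(read_structure(bad), "line 4")
})

test_that("vesicle GRO files carry species and a correct count line", {
  v <- place_lipids(vesicle_spec(n_lipids_total = 300, seed = 3))
  gro <- withr::local_tempfile(fileext = ".gro")
  write_structure(v, gro)
  expect_equal(as.integer(trimws(readLines(gro)[2])), 300)
  rv <- read_structure(gro)
  expect_equal(sort(unique(rv$species)), c("CDL", "DPPE", "DPPG"))
  expect_equal(as.integer(table(rv$species)[c("DPPE", "DPPG", "CDL")]),
               as.integer(table(v$lipids$species)[c("DPPE", "DPPG", "CL")]))
})

test_that("multi-model ensembles round trip in order", {
  ens <- make_bent_ensemble(n_res = 30, hinge = 15, angle = 20,
                            noise = 0.02, n_frames = 5, seed = 4)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, pdb)
  re <- read_ensemble(pdb)
  expect_length(re, 5)
  for (i in 1:5) {
    expect_lt(max(abs(re$coords[[i]] - ens$coords[[i]])), 1e-4)
  }
  # re-read ensemble gives the same recovered angles
  a1 <- bending_series(ens, hinge = 15)$angle
  a2 <- bending_series(re, hinge = 15)$angle
  expect_equal(a1, a2, tolerance = 1e-2)

  single <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ensemble_frame(ens, 1), single)
  e1 <- read_ensemble(single)
  expect_length(e1, 1)
})

test_that("topology mismatches across frame files name the offender", {
  a <- build_rod(rod_spec(n_residues_per_chain = 10, hinge_residue = 5))
  b <- build_rod(rod_spec(n_residues_per_chain = 12, hinge_residue = 5))
  fa <- withr::local_tempfile(fileext = ".pdb")
  fb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(a, fa)
  write_structure(b, fb)
  expect_error(read_ensemble(c(fa, fb)), "frame 2")
  ok <- read_ensemble(c(fa, fa))
  expect_length(ok, 2)
})

test_that("selections parse clauses and refuse silent empties", {
  rod <- build_rod(rod_spec(n_residues_per_chain = 50, hinge_residue = 25))
  expect_equal(nrow(select_particles(rod, "chain A")), 50)
  expect_equal(nrow(select_particles(rod, "chain A and resid 1:10")), 10)
  expect_equal(nrow(select_particles(rod, "resid 1,5,7-9")), 10)
  expect_equal(unique(select_particles(rod, "domain coiled_coil")$domain),
               "coiled_coil")
  expect_error(select_particles(rod, "chain Z"), "no particles")
  expect_equal(nrow(select_particles(rod, "chain Z", allow_empty = TRUE)), 0)
  expect_error(select_particles(rod, "banana 4"), "cannot parse")
})

test_that("duplicate residues within a chain are rejected", {
  df <- tibble::tibble(chain = "A", resid = c(1, 2, 2), domain = "d",
                       x = 1:3, y = 0, z = 0)
  expect_error(as_particle_model(df), "duplicate")
})
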