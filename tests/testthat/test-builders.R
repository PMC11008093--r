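# Deterministic builders: counts, topology, lattice geometry, scaling rules.

test_that("receptor and ligand counts follow the floor formulas", {
  expect_identical(n_receptors(10452, 0.20), 1045L)
  expect_identical(n_surface_beads(12), 1809L)
  expect_identical(n_ligands(12, 0.5), 904L)
  for (f in seq(0, 1, by = 0.1)) {
    expect_identical(n_receptors(10452, f), as.integer(floor(f * 5226)))
    expect_identical(n_ligands(9, f), as.integer(floor(f * floor(4 * pi * 81))))
  }
  # whole-membrane reading available as a switch
  expect_identical(n_receptors(10452, 0.20, basis = "membrane"), 2090L)
})

test_that("membrane topology is 3 beads / 2 bonds / 1 angle per lipid", {
  m <- build_membrane(4, receptor_fraction = 0.5, seed = 1)
  expect_equal(nrow(m$pos), 12)
  expect_equal(nrow(m$bonds), 8)
  expect_equal(nrow(m$angles), 4)
  expect_equal(sum(m$species == 3L), 1L)  # floor(0.5 * 2)
  # leaflet populations equal; receptors only in the upper leaflet
  m2 <- build_membrane(128, receptor_fraction = 0.25, seed = 2)
  heads <- which(m2$species %in% c(1L, 3L))
  up <- m2$pos[heads, 3] > m2$box[3] / 2
  expect_equal(sum(up), 64)
  recs <- which(m2$species == 3L)
  expect_length(recs, 16)
  expect_true(all(m2$pos[recs, 3] > m2$box[3] / 2))
  # boundary fractions
  expect_equal(sum(build_membrane(128, 0, seed = 1)$species == 3L), 0)
  expect_equal(sum(build_membrane(128, 1, seed = 1)$species == 3L), 64)
  expect_error(build_membrane(7), "even")
})

test_that("builders are deterministic under a fixed seed", {
  a <- build_membrane(128, 0.5, seed = 11)
  b <- build_membrane(128, 0.5, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$species,
                         build_membrane(128, 0.5, seed = 12)$species))
  n1 <- build_nanoparticle(7, 0.5, seed = 4)
  n2 <- build_nanoparticle(7, 0.5, seed = 4)
  expect_identical(n1, n2)
})

test_that("Fibonacci nanosphere has uniform ~1 sigma bead spacing on radius R", {
  for (R in c(7, 12)) {
    np <- build_nanoparticle(R, ligand_coverage = 0.5, seed = 1)
    n <- nrow(np$pos)
    expect_equal(n, n_surface_beads(R))
    rad <- sqrt(rowSums(np$pos^2))  # built about the origin
    expect_true(all(abs(rad - R) < 1e-10))
    # nearest-neighbour spacing: median within [0.8, 1.2], none below 0.5
    d <- as.matrix(dist(np$pos))
    diag(d) <- Inf
    nn <- apply(d, 1, min)
    expect_gt(min(nn), 0.5)
    expect_true(median(nn) > 0.8 && median(nn) < 1.2)
    expect_equal(sum(np$species == 5L), n_ligands(R, 0.5))
    expect_length(np$rigid_bodies[[1]], n)
  }
  expect_equal(sum(build_nanoparticle(7, 0, seed = 1)$species == 5L), 0)
  expect_error(build_nanoparticle(0.2), "radius|surface")
})

test_that("epsilon_LR scaling rules: constant total binding and valency rescale", {
  expect_equal(epsilon_for_constant_total_binding(904, 904 * 20), 20)
  expect_equal(epsilon_for_constant_total_binding(100, 0), 0)
  e1 <- epsilon_for_constant_total_binding(200, 1000)
  e2 <- epsilon_for_constant_total_binding(400, 1000)
  expect_equal(e1 / e2, 2)
  expect_error(epsilon_for_constant_total_binding(0, 10), "positive")

  expect_equal(rescale_epsilon_by_valency(20, 1), 20)
  # reported rescaled depths at the smallest and largest radii; the
  # inferred eps_o / X form reproduces the printed values to ~0.02
  expect_equal(rescale_epsilon_by_valency(20, 5.15), 3.87, tolerance = 0.02)
  expect_equal(rescale_epsilon_by_valency(20, 4.35), 4.59, tolerance = 0.01)
  expect_error(rescale_epsilon_by_valency(20, 0), "positive")
})

test_that("assemble_system places the sphere a gap above the upper heads", {
  m <- build_membrane(200, 0.5, Lz = 60, seed = 1)
  np <- build_nanoparticle(3.5, 0.5, seed = 1)
  sys <- assemble_system(m, np, gap = 3)
  nm <- nrow(m$pos)
  expect_equal(nrow(sys$pos), nm + nrow(np$pos))
  expect_identical(sys$rigid_bodies[[1]], seq_len(nrow(np$pos)) + nm)
  top_head <- max(m$pos[m$species %in% c(1L, 3L), 3])
  lowest_np <- min(sys$pos[-(1:nm), 3])
  expect_equal(lowest_np, top_head + 3, tolerance = 0.05)
  # lateral centring
  expect_equal(mean(sys$pos[-(1:nm), 1]), m$box[1] / 2, tolerance = 1e-6)
  expect_error(assemble_system(m, build_nanoparticle(20, 0.5)),
               "narrower|height")
})
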