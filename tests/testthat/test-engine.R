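# Integrator, neighbour search, barostat and energy bookkeeping.

test_that("neighbor_pairs matches the O(N^2) oracle and honours minimum image", {
  # two beads 0.9 apart -> one pair at cutoff 1
  st <- bare_state(rbind(c(1, 1, 1), c(1.9, 1, 1)), c(1, 1), c(10, 10, 10))
  expect_equal(nrow(neighbor_pairs(st, 1)), 1)
  expect_equal(nrow(neighbor_pairs(st, 0.8)), 0)
  # pair across the periodic boundary
  st2 <- bare_state(rbind(c(0.2, 5, 5), c(9.7, 5, 5)), c(1, 1), c(10, 10, 10))
  expect_equal(nrow(neighbor_pairs(st2, 1)), 1)
  # random 200-bead gas: identical pair set to the brute-force scan
  set.seed(42)
  pos <- cbind(runif(200, 0, 12), runif(200, 0, 12), runif(200, 0, 12))
  st3 <- bare_state(pos, rep(1, 200), c(12, 12, 12))
  got <- sort_pairs(neighbor_pairs(st3, 1.8))
  want <- sort_pairs(bf_pairs(pos, c(12, 12, 12), 1.8))
  expect_equal(unname(got), unname(want))
  expect_error(neighbor_pairs(st3, 7), "minimum image")
})

test_that("free streaming: zero force, thermostat off -> displacement v dt", {
  st <- bare_state(rbind(c(5, 5, 5)), 1, c(20, 20, 20),
                   vel = rbind(c(0.3, -0.2, 0.1)))
  ip <- integrator_params(seed = 1, thermostat = FALSE, barostat = FALSE)
  res <- run_simulation(st, forcefield(lr = NULL), ip, 100,
                        stride_thermo = 0, stride_valency = 0)
  expect_equal(res$state$pos[1, ], c(5, 5, 5) + c(0.3, -0.2, 0.1) * 1,
               tolerance = 1e-12)
  expect_equal(res$state$time, 1)
  # n_steps = 0 leaves the state untouched
  res0 <- run_simulation(st, forcefield(lr = NULL), ip, 0)
  expect_identical(res0$state, st)
})

test_that("trajectories are reproducible for a fixed seed", {
  m <- small_patch(50)
  ff <- forcefield(lr = NULL)
  r1 <- run_simulation(m, ff, integrator_params(seed = 99), 500,
                       stride_thermo = 100)
  r2 <- run_simulation(m, ff, integrator_params(seed = 99), 500,
                       stride_thermo = 100)
  expect_identical(r1$state$pos, r2$state$pos)
  expect_identical(r1$state$vel, r2$state$vel)
  expect_identical(r1$thermo, r2$thermo)
  r3 <- run_simulation(m, ff, integrator_params(seed = 100), 500,
                       stride_thermo = 100)
  expect_false(identical(r1$state$pos, r3$state$pos))
})

test_that("NVE conserves energy and momentum", {
  m <- small_patch(50)
  ff <- forcefield(lr = NULL)
  # brief thermalized prelude, then NVE
  pre <- run_simulation(m, ff, integrator_params(seed = 5), 2000,
                        stride_thermo = 0, stride_valency = 0)
  ip <- integrator_params(seed = 5, thermostat = FALSE, barostat = FALSE)
  res <- run_simulation(pre$state, ff, ip, 10000, stride_thermo = 50,
                        stride_valency = 0)
  etot <- res$thermo$pe + res$thermo$ke
  # secular drift rate (the bounded shadow-Hamiltonian oscillation is not
  # drift): fitted slope, expressed per bead over the 1e4-step run
  slope <- unname(coef(lm(etot ~ res$thermo$time))[2])
  drift <- abs(slope) * 100 / nrow(m$pos)
  expect_lt(drift, 1e-3)  # epsilon per bead over 1e4 steps
  # total momentum conserved to near round-off
  p0 <- colSums(pre$state$vel * pre$state$mass)
  p1 <- colSums(res$state$vel * res$state$mass)
  expect_lt(max(abs(p1 - p0)), 1e-8)
})

test_that("Langevin thermostat holds kinetic temperature at 1.00 +/- 0.02", {
  m <- small_patch(50)
  ff <- forcefield(lr = NULL)
  res <- run_simulation(m, ff, integrator_params(seed = 21), 100000,
                        stride_thermo = 50, stride_valency = 0)
  sel <- res$thermo$time >= 100  # discard the warm-up
  Tmean <- mean(res$thermo$temperature[sel])
  expect_equal(Tmean, 1.00, tolerance = 0.02)
})

test_that("lateral barostat rescales toward zero tension with the right sign", {
  ff <- forcefield(lr = NULL)
  ip <- integrator_params(seed = 1)
  # compressed patch: positive lateral pressure, box must grow
  mc <- build_membrane(128, 0, area_per_lipid = 0.95, Lz = 30, seed = 2)
  expect_gt(lateral_pressure(mc, ff), 0)
  st <- mc
  for (k in 1:5) {
    st2 <- apply_lateral_barostat(st, ff, ip)
    expect_true(all(st2$box[1:2] > st$box[1:2]))
    expect_equal(st2$box[3], st$box[3])
    st <- st2
  }
  # stretched patch: tension (negative lateral pressure), box must shrink
  ms <- build_membrane(128, 0, area_per_lipid = 1.45, Lz = 30, seed = 2)
  expect_lt(lateral_pressure(ms, ff), 0)
  expect_true(all(apply_lateral_barostat(ms, ff, ip)$box[1:2] < ms$box[1:2]))
})

test_that("engine potential energy matches the plain-R closed forms", {
  # membrane fragment plus a small nanoparticle, pair-mode coupling
  m <- build_membrane(18, receptor_fraction = 0.5, Lz = 30, seed = 8)
  np <- build_nanoparticle(1.5, ligand_coverage = 0.5, seed = 8)
  sys <- assemble_system(m, np, gap = 1)
  for (mode in c("pair", "bond")) {
    ff <- forcefield(lr = lr_params(mode = mode))
    if (mode == "bond") {
      # attach a couple of live bonds by hand
      g <- bf_binding_graph(sys, 2)
      sys$lr_bonds <- g[seq_len(min(2, nrow(g))), , drop = FALSE]
    }
    expect_equal(potential_energy(sys, ff)$total,
                 r_potential_energy(sys, ff), tolerance = 1e-9)
  }
})

test_that("overstretched bonds and bad species abort with a diagnostic", {
  m <- small_patch(50)
  # place two bonded beads beyond R0
  m$pos[m$bonds[1, 2], ] <- m$pos[m$bonds[1, 1], ] + c(1.51, 0, 0)
  expect_error(potential_energy(m, forcefield(lr = NULL)), "overstretched")
})
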