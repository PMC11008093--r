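# The valence-limiting algorithm: stochastic formation, distance-triggered
# rupture, cap enforcement, and the pair-mode equivalence limit.

# a ligand at the origin-ish and receptors at given offsets
lig_rec_state <- function(rec_offsets, lr_bonds = NULL) {
  pos <- rbind(c(10, 10, 10),
               t(vapply(rec_offsets, function(d) c(10, 10, 10) + d,
                        numeric(3))))
  st <- bare_state(pos, c(5L, rep(3L, length(rec_offsets))), c(20, 20, 20))
  if (!is.null(lr_bonds)) st$lr_bonds <- lr_bonds
  st
}

test_that("bonds form within r_form with probability p_form", {
  st <- lig_rec_state(list(c(1, 0, 0)))  # pair at 1.0 sigma
  p1 <- lr_params(p_form = 1)
  res <- update_bonds(st, p1, seed = 1)
  expect_equal(nrow(res$state$lr_bonds), 1)
  expect_equal(res$events$event, "formed")
  expect_equal(res$events$r, 1, tolerance = 1e-12)
  p0 <- lr_params(p_form = 0)
  expect_equal(nrow(update_bonds(st, p0, seed = 1)$state$lr_bonds), 0)
  # the default 50% rule: formation frequency over many independent draws
  formed <- vapply(1:400, function(s) {
    nrow(update_bonds(st, lr_params(), seed = s)$state$lr_bonds)
  }, numeric(1))
  expect_equal(mean(formed), 0.5, tolerance = 0.08)
  # outside the search radius nothing happens even with p_form = 1
  far <- lig_rec_state(list(c(2.5, 0, 0)))
  expect_equal(nrow(update_bonds(far, p1, seed = 1)$state$lr_bonds), 0)
})

test_that("live bonds rupture beyond r_break and the event records r", {
  st <- lig_rec_state(list(c(1.6, 0, 0)), lr_bonds = cbind(1L, 2L))
  res <- update_bonds(st, lr_params(p_form = 0), seed = 3)
  expect_equal(nrow(res$state$lr_bonds), 0)
  expect_equal(res$events$event, "broken")
  expect_gt(res$events$r, 1.5)
  # at 1.4 sigma the bond survives
  ok <- lig_rec_state(list(c(1.4, 0, 0)), lr_bonds = cbind(1L, 2L))
  expect_equal(nrow(update_bonds(ok, lr_params(p_form = 0), seed = 3)$state$lr_bonds), 1)
})

test_that("the valence cap limits a contested ligand to one bond", {
  st <- lig_rec_state(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  p1 <- lr_params(p_form = 1)
  for (s in 1:20) {
    res <- update_bonds(st, p1, seed = s)
    expect_equal(nrow(res$state$lr_bonds), 1)  # cap saturation, any seed
  }
  # which receptor wins varies with the seed (random traversal order)
  winners <- vapply(1:40, function(s) {
    update_bonds(st, p1, seed = s)$state$lr_bonds[1, 2]
  }, integer(1))
  expect_gt(length(unique(winners)), 1)
  # with the cap lifted all three receptors attach
  pinf <- lr_params(p_form = 1, valence_cap = Inf)
  expect_equal(nrow(update_bonds(st, pinf, seed = 1)$state$lr_bonds), 3)
})

test_that("binding graph matches the brute-force adjacency in pair mode", {
  set.seed(7)
  pos <- cbind(runif(20, 0, 8), runif(20, 0, 8), runif(20, 0, 8))
  st <- bare_state(pos, rep(c(5L, 3L), 10), c(8, 8, 8))
  p <- lr_params(mode = "pair")
  got <- sort_pairs(binding_graph(st, p))
  want <- sort_pairs(bf_binding_graph(st, lr_binding_cutoff(p)))
  expect_equal(unname(got), unname(want))
  # bond mode returns exactly the live bond set
  stb <- st
  stb$lr_bonds <- cbind(c(1L, 3L), c(2L, 4L))
  expect_equal(binding_graph(stb, lr_params(mode = "bond")), stb$lr_bonds)
  empty <- binding_graph(st, lr_params(mode = "bond"))
  expect_equal(nrow(empty), 0)
})

test_that("bond mode converges to pair mode in the equivalence limit", {
  # cap = Inf, p_form = 1, r_form = binding cutoff: one update must
  # reproduce the pair-mode binding graph exactly
  set.seed(11)
  for (rep in 1:5) {
    pos <- cbind(runif(30, 0, 9), runif(30, 0, 9), runif(30, 0, 9))
    st <- bare_state(pos, rep(c(5L, 3L), 15), c(9, 9, 9))
    ppair <- lr_params(mode = "pair")
    pbond <- lr_params(mode = "bond", p_form = 1, valence_cap = Inf,
                       r_form = lr_binding_cutoff(ppair))
    res <- update_bonds(st, pbond, seed = rep)
    got <- sort_pairs(res$state$lr_bonds)
    want <- sort_pairs(binding_graph(st, ppair))
    expect_equal(unname(got), unname(want))
  }
})

test_that("event bookkeeping balances the live bond count during a run", {
  m <- build_membrane(72, receptor_fraction = 1, Lz = 40, seed = 13)
  np <- build_nanoparticle(2, ligand_coverage = 1, seed = 13)
  sys <- assemble_system(m, np, gap = 1)
  sys <- thermalize_velocities(sys, 1, 13)
  ff <- forcefield(lr = lr_params(mode = "bond"))
  res <- run_simulation(sys, ff, integrator_params(seed = 13), 3000,
                        stride_thermo = 500, stride_valency = 100)
  formed <- sum(res$events$event == "formed")
  broken <- sum(res$events$event == "broken")
  expect_gt(formed, 0)
  expect_equal(formed - broken, nrow(res$state$lr_bonds))
  # the cap holds in the final state: no bead appears twice
  expect_false(any(duplicated(c(res$state$lr_bonds))))
  # and the sampled mean valency never exceeds the cap
  expect_true(all(res$valency$mean_valency <= 1 + 1e-12))
})
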