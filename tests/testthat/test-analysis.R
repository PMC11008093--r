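# Valency statistics, wrapping detection, percent error, the energy
# diagnostic, and membrane observables.

test_that("ligand_valency tallies the binding graph per ligand", {
  # 5 ligands, 8 receptors at hand-placed distances
  set.seed(19)
  lig <- cbind(runif(5, 2, 10), runif(5, 2, 10), runif(5, 2, 10))
  rec <- cbind(runif(8, 2, 10), runif(8, 2, 10), runif(8, 2, 10))
  st <- bare_state(rbind(lig, rec), c(rep(5L, 5), rep(3L, 8)),
                   c(12, 12, 12))
  p <- lr_params(mode = "pair")
  v <- ligand_valency(st, p)
  g <- bf_binding_graph(st, lr_binding_cutoff(p))
  want <- vapply(1:5, function(l) sum(g[, 1] == l), numeric(1))
  expect_equal(unname(v$counts), want)
  expect_equal(v$mean, nrow(g) / 5)
  # no receptors in range -> all zero
  far <- bare_state(rbind(lig, rec + 100), c(rep(5L, 5), rep(3L, 8)),
                    c(300, 300, 300))
  expect_equal(ligand_valency(far, p)$mean, 0)
  # valency is invariant under a rigid shift of the whole frame
  sh <- st
  sh$pos <- sweep(st$pos, 2, c(1.3, -0.7, 0.4), "+")
  expect_equal(ligand_valency(sh, p)$counts, v$counts)
  expect_error(ligand_valency(bare_state(rec, rep(3L, 8), c(12, 12, 12)), p),
               "no ligand")
})

test_that("time-averaged valency averages frame means over the post-wrap window", {
  v <- data.frame(time = seq(0, 1000, by = 10), mean_valency = 3,
                  bound_fraction = 1)
  expect_equal(time_averaged_valency(v, wrap_time = 200), 3)
  v2 <- data.frame(time = c(100, 200, 300, 400),
                   mean_valency = c(9, 9, 4, 6))
  expect_equal(time_averaged_valency(v2, wrap_time = 200, equil = 100), 5)
  expect_error(time_averaged_valency(v2, wrap_time = 400), "extend the run")
  expect_error(time_averaged_valency(v2, wrap_time = NA), "NA")
})

test_that("wrapping_time finds the first sustained threshold crossing", {
  tt <- seq(0, 2000, by = 10)
  bf <- ifelse(tt >= 500, 1, 0)
  v <- data.frame(time = tt, bound_fraction = bf)
  expect_equal(wrapping_time(v), 500)
  # a spike that is not sustained is ignored
  bf2 <- ifelse(tt >= 800, 0.97, ifelse(tt == 300, 1, 0.1))
  expect_equal(wrapping_time(data.frame(time = tt, bound_fraction = bf2)),
               800)
  # never wrapped
  expect_true(is.na(wrapping_time(data.frame(time = tt,
                                             bound_fraction = rep(0.5, length(tt))))))
  # raising the threshold never decreases the wrapping time
  set.seed(31)
  for (k in 1:10) {
    prof <- cummax(pmin(1, cumsum(runif(201, 0, 0.02))))
    vd <- data.frame(time = tt[1:201], bound_fraction = prof)
    t_lo <- wrapping_time(vd, threshold = 0.6)
    t_hi <- wrapping_time(vd, threshold = 0.9)
    expect_true(is.na(t_lo) || is.na(t_hi) || t_hi >= t_lo)
    if (is.na(t_lo)) expect_true(is.na(t_hi))
  }
})

test_that("percent error of the valence-unlimited wrapping time", {
  expect_equal(percent_error(700, 700), 0)
  expect_equal(percent_error(350, 700), -50)
  expect_equal(percent_error(1400, 700), 100)
  for (x in c(1, 10, 1234)) expect_equal(percent_error(x, x), 0)
  # monotone increasing in Tu_NV
  expect_true(all(diff(percent_error(seq(100, 1000, by = 50), 400)) > 0))
  expect_error(percent_error(100, 0), "positive")
  r <- wrapping_report(c(800, NA, 900), c(400, 500, 450))
  expect_equal(r$percent_error, c(100, NA, 100))
  expect_false(r$wrapped[2])
  expect_equal(attr(r, "mean_percent_error"), 100)
})

test_that("energy-difference diagnostic approximates the measured valency", {
  expect_equal(valency_from_energy(-100, -100, 20, 10), 1)
  # one extra full-depth receptor per ligand: U_pair lower by eps * N_L
  expect_equal(valency_from_energy(-100 - 20 * 10, -100, 20, 10), 2)
  expect_error(valency_from_energy(-1, -1, 20, 0), "N_L")
  # cross-check against the direct count on a constructed bound cluster:
  # each of 3 ligands sits in the plateau of `k` receptors
  counts <- c(3, 2, 4)
  pos <- c(); species <- c()
  centers <- rbind(c(5, 5, 5), c(15, 5, 5), c(10, 15, 5))
  for (i in 1:3) {
    pos <- rbind(pos, centers[i, ])
    species <- c(species, 5L)
    for (k in seq_len(counts[i])) {
      ang <- 2 * pi * k / counts[i]
      pos <- rbind(pos, centers[i, ] + 1.05 * c(cos(ang), sin(ang), 0))
      species <- c(species, 3L)
    }
  }
  st <- bare_state(pos, species, c(25, 25, 25))
  ppair <- lr_params(mode = "pair")
  X_direct <- ligand_valency(st, ppair)$mean
  U_pair <- potential_energy(st, forcefield(lr = ppair))$lr_pair
  # the matched bond-mode system: one bond per ligand, same geometry
  stb <- st
  lig_idx <- which(species == 5L)
  first_rec <- lig_idx + 1L
  stb$lr_bonds <- cbind(lig_idx, first_rec)
  U_bond <- potential_energy(stb, forcefield(lr = lr_params(mode = "bond")))$lr_bond
  est <- valency_from_energy(U_pair, U_bond, 20, 3)
  expect_equal(est, X_direct, tolerance = 0.5)
})

test_that("area per lipid and the extrapolated box edge", {
  th <- data.frame(time = seq(0, 100, by = 1), Lx = 77, Ly = 77)
  apl <- area_per_lipid(th, 10452)
  expect_equal(apl$area_per_lipid, 77^2 / 5226)
  expect_equal(apl$edge_for(10452), 77)
  expect_equal(apl$edge_for(2 * 10452), 77 * sqrt(2))
  expect_error(area_per_lipid(th, 10452, window = c(500, 600)), "empty")
})
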