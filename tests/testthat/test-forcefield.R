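# Closed-form potentials: values, cutoff continuity, and force-energy
# consistency against central differences.

test_that("WCA potential has the exact closed form and a continuous cutoff", {
  p <- wca_params(epsilon = 1, b = 1)
  expect_equal(p$r_c, 2^(1 / 6))
  expect_equal(wca_energy(1, p), 1)              # U(b) = epsilon
  expect_equal(wca_energy(p$r_c, p), 0)
  expect_equal(wca_energy(10, p), 0)
  # continuity and smoothness at the cutoff
  eps <- 1e-9
  expect_lt(abs(wca_energy(p$r_c - eps, p)), 1e-6)
  expect_lt(abs(wca_force(p$r_c - eps, p)), 1e-6)
  expect_error(wca_energy(0, p), "r > 0")
  # species-dependent b
  p95 <- wca_params(b = 0.95)
  expect_equal(wca_energy(0.95, p95), 1)
  expect_equal(p95$r_c, 2^(1 / 6) * 0.95)
})

test_that("FENE bond matches the logarithmic form and rejects overstretch", {
  p <- fene_params()  # K = 30, R0 = 1.5
  expect_equal(fene_energy(0.75, p, include_wca = FALSE),
               -0.5 * 30 * 1.5^2 * log(1 - 0.25), tolerance = 1e-12)
  # the log term vanishes as r -> 0; the folded-in repulsion diverges
  expect_lt(abs(fene_energy(1e-4, p, include_wca = FALSE)), 1e-6)
  expect_gt(fene_energy(1e-2, p), 1e10)
  expect_gt(fene_energy(1.49, p), 100)           # finite but enormous
  expect_error(fene_energy(1.5, p), "overstretched")
  expect_error(fene_energy(1.6, p), "overstretched")
})

test_that("harmonic angle is zero at 180 degrees and symmetric", {
  p <- angle_params()  # K = 10, theta0 = pi
  expect_equal(angle_energy(pi, p), 0)
  expect_equal(angle_energy(pi - 0.1, p), 10 * 0.01, tolerance = 1e-12)
  p2 <- angle_params(K = 7, theta0 = pi / 2)
  for (d in c(0.05, 0.3, 1.2)) {
    expect_equal(angle_energy(pi / 2 + d, p2), angle_energy(pi / 2 - d, p2))
  }
  expect_error(angle_energy(3.5, p), "0, pi")
})

test_that("cosine attraction: plateau, half-depth midpoint, zero beyond", {
  p <- cosine_params(epsilon = 1, r_c = 2^(1 / 6), w_c = 1.5)
  expect_equal(cosine_attraction_energy(p$r_c, p), -1)
  expect_equal(cosine_attraction_energy(0.5, p), -1)
  expect_equal(cosine_attraction_energy(p$r_c + p$w_c, p), 0,
               tolerance = 1e-12)
  expect_equal(cosine_attraction_energy(p$r_c + p$w_c / 2, p), -0.5,
               tolerance = 1e-12)
  expect_equal(cosine_attraction_energy(5, p), 0)
  # monotone non-decreasing on the decay
  r <- seq(p$r_c, p$r_c + p$w_c, length.out = 200)
  expect_true(all(diff(cosine_attraction_energy(r, p)) >= 0))
  expect_error(cosine_params(w_c = 0), "w_c > 0")
})

test_that("forces equal -dU/dr to 1e-6 relative accuracy away from cutoffs", {
  cases <- list(
    list(f = wca_energy, g = wca_force, p = wca_params(b = 0.95),
         r = c(0.7, 0.9, 1.0, 1.05)),
    list(f = cosine_attraction_energy, g = cosine_attraction_force,
         p = cosine_params(), r = c(1.2, 1.6, 2.0, 2.5)),
    list(f = function(r, p) fene_energy(r, p),
         g = function(r, p) fene_force(r, p), p = fene_params(),
         r = c(0.6, 0.9, 1.1, 1.4)),
    list(f = ligand_receptor_energy, g = ligand_receptor_force,
         p = lr_params(), r = c(1.2, 1.35, 1.5))
  )
  for (cs in cases) {
    for (r in cs$r) {
      fn <- num_deriv(function(x) cs$f(x, cs$p), r)
      fa <- cs$g(r, cs$p)
      expect_equal(fa, -fn, tolerance = 1e-6)
    }
  }
})

test_that("ligand-receptor geometry reproduces the 1.25-epsilon rupture energy", {
  p <- lr_params()  # depth 20, onset 2^(1/6), width 0.45
  expect_equal(abs(ligand_receptor_energy(1.5, p)), 1.25, tolerance = 0.01)
  expect_equal(ligand_receptor_energy(2^(1 / 6), p), -20)
  expect_equal(ligand_receptor_energy(2, p), 0)
  expect_equal(lr_binding_cutoff(p), 2^(1 / 6) + 0.45)
  # identical function in both coupling modes
  r <- seq(0.9, 2, by = 0.05)
  expect_identical(ligand_receptor_energy(r, lr_params(mode = "pair")),
                   ligand_receptor_energy(r, lr_params(mode = "bond")))
  expect_error(lr_params(r_break = 2.5), "r_break")
})

test_that("tabulated bond potential matches the analytic form", {
  p <- lr_params()
  tab <- tabulate_bond_potential(p, n_points = 2000)
  expect_equal(nrow(tab), 2000)
  expect_equal(max(tab$r), p$r_form)
  plateau <- tab$r <= p$r_c
  expect_true(all(tab$U[plateau] == -p$epsilon))
  expect_true(all(tab$F[plateau] == 0))
  # linear interpolation at the rupture length within 1e-3 epsilon
  u_interp <- approx(tab$r, tab$U, xout = 1.5)$y
  expect_equal(u_interp, ligand_receptor_energy(1.5, p), tolerance = 1e-3)
  expect_equal(abs(u_interp), 1.25, tolerance = 0.01)
  # tabulated force is the analytic derivative, not a finite difference
  i <- which.min(abs(tab$r - 1.3))
  expect_equal(tab$F[i], ligand_receptor_force(tab$r[i], p))
  expect_error(tabulate_bond_potential(p, n_points = 1), "n_points")
})
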