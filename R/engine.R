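# R surface over the compiled MD core: integration, barostat, neighbour
# search, and velocity initialisation.

#' Integrator parameters
#'
#' Langevin dynamics in the velocity-Verlet scheme with the thermostat
#' applied as a friction-plus-noise force (the convention of the common
#' MD engines), and a Berendsen-style lateral barostat that relaxes the
#' xy box dimensions toward zero lateral tension with time constant
#' `pdamp` while `Lz` stays fixed.
#'
#' @param dt Timestep (tau). Default 0.01.
#' @param kT Target temperature (epsilon/k_B). Default 1.
#' @param damp Langevin damping time (tau). Default 1.
#' @param pdamp Barostat relaxation time (tau). Default 1000.
#' @param P_lateral Target lateral pressure (epsilon/sigma^3). Default 0
#'   (tensionless membrane).
#' @param seed Integer seed for the thermostat noise and the dynamic-bond
#'   stochastics. The stream is independent of R's RNG; a given
#'   (state, seed) pair reproduces a trajectory bitwise.
#' @param thermostat,barostat Logical switches. Turning both off gives
#'   plain NVE velocity-Verlet.
#' @return An object of class `integrator_params`.
#' @export
integrator_params <- function(dt = 0.01, kT = 1, damp = 1, pdamp = 1000,
                              P_lateral = 0, seed = 1, thermostat = TRUE,
                              barostat = TRUE) {
  stopifnot(dt > 0, damp > 0, pdamp > 0, kT >= 0)
  structure(list(dt = dt, kT = kT, damp = damp, pdamp = pdamp,
                 P_lateral = P_lateral, seed = as.double(seed),
                 thermostat = thermostat, barostat = barostat),
            class = "integrator_params")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Free beads receive independent Gaussian velocity components at
#' temperature `kT`; rigid-body beads are left at rest (the thermostat
#' equilibrates the body's six degrees of freedom during the run).
#'
#' @param state A `system_state`.
#' @param kT Temperature (epsilon/k_B).
#' @param seed Seed for the draw.
#' @return The state with velocities replaced.
#' @export
thermalize_velocities <- function(state, kT = 1, seed = 1) {
  stopifnot(inherits(state, "system_state"))
  n <- nrow(state$pos)
  rigid <- unlist(state$rigid_bodies)
  v <- with_seed(seed, matrix(stats::rnorm(3 * n), n, 3))
  v <- v * sqrt(kT / state$mass)
  if (length(rigid)) v[rigid, ] <- 0
  free <- setdiff(seq_len(n), rigid)
  if (length(free) > 1) {  # remove the net drift of the free beads
    v[free, ] <- sweep(v[free, , drop = FALSE], 2,
                       colMeans(v[free, , drop = FALSE]))
  }
  state$vel <- v
  state
}

#' Run the simulation
#'
#' Advances the system `n_steps` timesteps, invoking the dynamic-bond
#' hook once per step when the force field's ligand-receptor coupling is
#' in bond mode, and sampling observables at fixed strides.
#'
#' @param state A `system_state` (from the builders or a previous run).
#' @param ff A [forcefield()].
#' @param ip An [integrator_params()].
#' @param n_steps Number of timesteps (>= 0).
#' @param stride_thermo Steps between thermodynamic samples (time,
#'   temperature, potential/kinetic energy, lateral pressure, box).
#'   Default 100 (1 tau at the default timestep); 0 disables.
#' @param stride_valency Steps between valency/bound-fraction samples.
#'   Default 100; 0 disables.
#' @param stride_traj Steps between stored trajectory frames. Default
#'   1000 (10 tau); only used when `keep_trajectory = TRUE`.
#' @param keep_trajectory Store coordinate frames in memory.
#' @param log_events Record individual bond formation/rupture events.
#' @return An object of class `sim_result`: a list with the final
#'   `state`, data.frames `thermo`, `valency` and `events`, and (if
#'   requested) `trajectory` (list of frames with times and box sizes).
#' @export
run_simulation <- function(state, ff, ip, n_steps,
                           stride_thermo = 100, stride_valency = 100,
                           stride_traj = 1000, keep_trajectory = FALSE,
                           log_events = TRUE) {
  stopifnot(inherits(state, "system_state"), inherits(ff, "forcefield"),
            inherits(ip, "integrator_params"), n_steps >= 0)
  support <- if (is.null(ff$lr)) 0 else lr_binding_cutoff(ff$lr)
  opts <- list(stride_thermo = as.integer(stride_thermo),
               stride_valency = as.integer(stride_valency),
               stride_traj = as.integer(stride_traj),
               keep_trajectory = keep_trajectory,
               log_events = log_events,
               lr_support = support,
               measure_valency = !is.null(ff$lr))
  if (n_steps == 0) {
    return(structure(list(state = state,
                          thermo = data.frame(), valency = data.frame(),
                          events = data.frame(), trajectory = NULL),
                     class = "sim_result"))
  }
  res <- cpp_run(state, ff, ip, as.integer(n_steps), opts)
  out <- list(state = res$state,
              thermo = as.data.frame(res$thermo),
              valency = as.data.frame(res$valency),
              events = as.data.frame(res$events,
                                     stringsAsFactors = FALSE),
              trajectory = if (keep_trajectory) res$trajectory else NULL)
  structure(out, class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result: t =", x$state$time, "tau |",
      nrow(x$thermo), "thermo samples |",
      nrow(x$valency), "valency samples |",
      nrow(x$events), "bond events\n")
  if (nrow(x$thermo) > 0) {
    n <- nrow(x$thermo)
    w <- x$thermo[max(1, n - 9):n, ]
    cat(sprintf("  recent: T = %.3f, PE = %.1f, P_lat = %+.4f, box = %.2f x %.2f\n",
                mean(w$temperature), mean(w$pe), mean(w$p_lateral),
                w$Lx[nrow(w)], w$Ly[nrow(w)]))
  }
  invisible(x)
}

#' Minimum-image neighbour pairs
#'
#' All unordered bead pairs with minimum-image separation strictly below
#' `cutoff`, computed with a cell list. The cutoff must respect the
#' minimum-image convention (at most half the smallest box length).
#'
#' @param state A `system_state` (or any list with `pos` and `box`).
#' @param cutoff Search radius (sigma).
#' @return Two-column integer matrix of 1-based bead indices, `i < j`.
#' @export
neighbor_pairs <- function(state, cutoff) {
  stopifnot(cutoff > 0)
  cpp_neighbor_pairs(state$pos, state$box, cutoff)
}

#' Potential energy of a configuration
#'
#' Evaluates the full force field on a static configuration, split by
#' term. The ligand-receptor contribution appears under `lr_pair` (pair
#' mode) or `lr_bond` (bond mode, live bonds only).
#'
#' @param state A `system_state`.
#' @param ff A [forcefield()].
#' @return A list: `total`, `pair`, `bond`, `angle`, `lr_pair`, `lr_bond`
#'   (epsilon units).
#' @export
potential_energy <- function(state, ff) {
  stopifnot(inherits(state, "system_state"), inherits(ff, "forcefield"))
  cpp_potential_energy(state, ff)
}

#' Instantaneous lateral pressure
#'
#' Kinetic plus virial xy pressure, `(P_xx + P_yy) / 2`, over the full
#' box volume.
#'
#' @inheritParams potential_energy
#' @return Pressure in epsilon/sigma^3.
#' @export
lateral_pressure <- function(state, ff) {
  stopifnot(inherits(state, "system_state"), inherits(ff, "forcefield"))
  cpp_lateral_pressure(state, ff)
}

#' Apply one lateral barostat rescale
#'
#' One Berendsen-style relaxation step toward the target lateral
#' pressure: the xy box lengths and in-plane coordinates are scaled by
#' `mu = 1 + dt / (3 pdamp) (P_lat - P0) Lz`; `Lz` is untouched.  The
#' coupling acts on the areal tension `P_lat * Lz`, so the relaxation
#' rate does not depend on the empty height of the box.  The same update
#' runs inside [run_simulation()] every timestep when the barostat is
#' enabled.
#'
#' @inheritParams potential_energy
#' @param ip An [integrator_params()].
#' @return The rescaled `system_state`.
#' @export
apply_lateral_barostat <- function(state, ff, ip) {
  stopifnot(inherits(ip, "integrator_params"))
  P <- lateral_pressure(state, ff)
  mu <- 1 + ip$dt / (3 * ip$pdamp) * (P - ip$P_lateral) * state$box[3]
  cut <- 2 * (lr_support_cutoff(ff) + 0.3)
  if (mu * min(state$box[1:2]) < cut) {
    stop("barostat rescale would shrink the box below twice the interaction cutoff")
  }
  rigid <- unlist(state$rigid_bodies)
  state$box[1:2] <- state$box[1:2] * mu
  if (length(rigid)) {
    free <- setdiff(seq_len(nrow(state$pos)), rigid)
    state$pos[free, 1:2] <- state$pos[free, 1:2] * mu
    ctr <- colMeans(state$pos[rigid, , drop = FALSE])
    shift <- c(ctr[1:2] * (mu - 1), 0)
    state$pos[rigid, ] <- sweep(state$pos[rigid, , drop = FALSE], 2, shift, "+")
  } else {
    state$pos[, 1:2] <- state$pos[, 1:2] * mu
  }
  state
}

# largest pair-interaction cutoff of a force field (sigma)
lr_support_cutoff <- function(ff) {
  cut <- max(2^(1 / 6) * ff$b, ff$tail_cos$r_c + ff$tail_cos$w_c)
  if (!is.null(ff$lr)) cut <- max(cut, lr_binding_cutoff(ff$lr), ff$lr$r_form)
  cut
}
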