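# Experiment configuration: declarative, serializable descriptions of a
# run (membrane, nanoparticle, coupling, integrator, replicates) plus the
# named presets for the standard experiments.

#' Experiment configuration
#'
#' A declarative description of one simulation condition.  Configs are
#' plain nested lists, serializable to YAML with [save_config()] and
#' round-trippable with [load_config()].  Replicate `i` runs with seed
#' `base_seed + i - 1` (independent thermostat/bond streams).
#'
#' @param n_lipids Membrane size (lipid count, even).
#' @param receptor_fraction Receptor fraction of the facing leaflet.
#' @param radius Nanosphere radius (sigma); `NULL` for a membrane-only
#'   run.
#' @param ligand_coverage Fraction of surface beads that are ligands.
#' @param epsilon_LR Ligand-receptor well depth (epsilon).
#' @param mode Coupling scheme, `"pair"` or `"bond"`.
#' @param run_tau Run length (tau).
#' @param replicates Number of replicates. Default 5.
#' @param base_seed Base seed; replicate i uses `base_seed + i - 1`.
#' @param dt,kT,damp,pdamp Integrator settings (see
#'   [integrator_params()]).
#' @param w_c Tail-tail attraction width (sigma).
#' @param area_per_lipid Initial lattice area per lipid (sigma^2).
#' @param stride_thermo_tau,stride_traj_tau,stride_valency_tau Output
#'   strides in tau.
#' @param label Optional condition label.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_lipids = 1000, receptor_fraction = 0.5,
                              radius = NULL, ligand_coverage = 0.5,
                              epsilon_LR = 20, mode = c("pair", "bond"),
                              run_tau = 1000, replicates = 5,
                              base_seed = 1, dt = 0.01, kT = 1, damp = 1,
                              pdamp = 1000, w_c = 1.5,
                              area_per_lipid = 1.2,
                              stride_thermo_tau = 1, stride_traj_tau = 10,
                              stride_valency_tau = 1, label = "") {
  mode <- match.arg(mode)
  cfg <- list(n_lipids = as.integer(n_lipids),
              receptor_fraction = receptor_fraction,
              radius = radius, ligand_coverage = ligand_coverage,
              epsilon_LR = epsilon_LR, mode = mode,
              run_tau = run_tau, replicates = as.integer(replicates),
              base_seed = as.integer(base_seed), dt = dt, kT = kT,
              damp = damp, pdamp = pdamp, w_c = w_c,
              area_per_lipid = area_per_lipid,
              stride_thermo_tau = stride_thermo_tau,
              stride_traj_tau = stride_traj_tau,
              stride_valency_tau = stride_valency_tau, label = label)
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("experiment_config", if (nzchar(x$label)) paste0("[", x$label, "]"),
      "\n")
  cat(sprintf("  membrane: %d lipids, %.0f%% receptors | np: %s | LR: eps=%g mode=%s\n",
              x$n_lipids, 100 * x$receptor_fraction,
              if (is.null(x$radius)) "none"
              else sprintf("R=%g, coverage=%.0f%%", x$radius,
                           100 * x$ligand_coverage),
              x$epsilon_LR, x$mode))
  cat(sprintf("  run: %g tau x %d replicates, base seed %d\n", x$run_tau,
              x$replicates, x$base_seed))
  invisible(x)
}

#' Save / load an experiment configuration
#'
#' YAML on disk; `load_config(save_config(cfg))` reproduces `cfg`.
#'
#' @param config An [experiment_config()].
#' @param path File path.
#' @return `save_config` returns `path` invisibly; `load_config` the
#'   configuration.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$n_lipids <- as.integer(cfg$n_lipids)
  cfg$replicates <- as.integer(cfg$replicates)
  cfg$base_seed <- as.integer(cfg$base_seed)
  if (is.null(cfg$label)) cfg$label <- ""
  structure(cfg, class = "experiment_config")
}

#' Short provenance hash of a configuration
#'
#' FNV-1a hash of the canonical text serialization, for embedding in run
#' summaries.
#'
#' @param config An [experiment_config()].
#' @return An 8-hex-digit string.
#' @export
config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(unclass(config))),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Materialize a configuration into state and force field
#'
#' Builds the membrane (and nanoparticle, if any), assembles the system,
#' thermalizes velocities, and constructs the matching force field and
#' integrator parameters for a given replicate.
#'
#' @param config An [experiment_config()].
#' @param replicate Replicate index (1-based); sets the seed
#'   `base_seed + replicate - 1`.
#' @return A list: `state`, `ff`, `ip`, `seed`.
#' @export
build_experiment <- function(config, replicate = 1) {
  stopifnot(inherits(config, "experiment_config"), replicate >= 1)
  seed <- config$base_seed + replicate - 1
  mem <- build_membrane(config$n_lipids,
                        receptor_fraction = config$receptor_fraction,
                        area_per_lipid = config$area_per_lipid,
                        seed = seed)
  state <- mem
  lr <- NULL
  if (!is.null(config$radius)) {
    np <- build_nanoparticle(config$radius,
                             ligand_coverage = config$ligand_coverage,
                             seed = seed)
    state <- assemble_system(mem, np)
    lr <- lr_params(epsilon_LR = config$epsilon_LR, mode = config$mode)
  }
  state <- thermalize_velocities(state, kT = config$kT, seed = seed)
  ff <- forcefield(w_c = config$w_c, lr = lr)
  ip <- integrator_params(dt = config$dt, kT = config$kT,
                          damp = config$damp, pdamp = config$pdamp,
                          seed = seed)
  list(state = state, ff = ff, ip = ip, seed = seed)
}

#' Run all replicates of a configuration
#'
#' Executes every replicate of a condition and (optionally) writes the
#' standard outputs per replicate into `outdir`: trajectory dump,
#' thermo/valency tables, bond-event log, checkpoint and a JSON run
#' summary embedding the config hash and seed.
#'
#' @param config An [experiment_config()].
#' @param outdir Output directory, or `NULL` to keep results in memory
#'   only.
#' @param keep_trajectory Store trajectory frames (memory!).
#' @param progress Print per-replicate progress lines.
#' @return A list of `sim_result` objects (one per replicate), with the
#'   per-replicate analysis attached as attribute `summary`.
#' @export
run_experiment <- function(config, outdir = NULL, keep_trajectory = FALSE,
                           progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  steps_per_tau <- round(1 / config$dt)
  n_steps <- round(config$run_tau * steps_per_tau)
  hash <- config_hash(config)
  results <- vector("list", config$replicates)
  for (rep in seq_len(config$replicates)) {
    bl <- build_experiment(config, rep)
    res <- run_simulation(
      bl$state, bl$ff, bl$ip, n_steps,
      stride_thermo = max(1, round(config$stride_thermo_tau * steps_per_tau)),
      stride_valency = max(1, round(config$stride_valency_tau * steps_per_tau)),
      stride_traj = max(1, round(config$stride_traj_tau * steps_per_tau)),
      keep_trajectory = keep_trajectory)
    smry <- summarize_run(res, config, seed = bl$seed, hash = hash)
    attr(res, "summary") <- smry
    if (!is.null(outdir)) {
      tag <- sprintf("rep%02d", rep)
      utils::write.table(res$thermo, file.path(outdir, paste0(tag, "_thermo.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(res$valency, file.path(outdir, paste0(tag, "_valency.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      write_bond_events(res$events, file.path(outdir, paste0(tag, "_events.tsv")))
      write_checkpoint(res$state, file.path(outdir, paste0(tag, "_checkpoint.txt")))
      if (keep_trajectory) {
        write_xyz(res, file.path(outdir, paste0(tag, "_traj.xyz")))
      }
      write_run_summary(smry, file.path(outdir, paste0(tag, "_summary.json")))
    }
    if (progress) {
      message(sprintf("replicate %d/%d done (t = %g tau)", rep,
                      config$replicates, res$state$time))
    }
    results[[rep]] <- res
  }
  results
}

#' Summarize one run
#'
#' Scalar observables of a finished replicate: mean temperature, area
#' per lipid, wrapping time (if a nanoparticle is present), and the
#' time-averaged valency over the post-wrap window.
#'
#' @param result A `sim_result`.
#' @param config The [experiment_config()] that produced it.
#' @param seed,hash Provenance fields for the summary.
#' @return A named list (JSON-ready, see [write_run_summary()]).
#' @export
summarize_run <- function(result, config, seed = NA, hash = "") {
  th <- result$thermo
  half <- th$time >= (min(th$time) + max(th$time)) / 2
  apl <- area_per_lipid(th, config$n_lipids)
  out <- list(label = config$label, config_hash = hash, seed = seed,
              version = as.character(utils::packageVersion("memwrap")),
              time_tau = result$state$time,
              mean_temperature = mean(th$temperature[half]),
              mean_lateral_pressure = mean(th$p_lateral[half]),
              area_per_lipid = apl$area_per_lipid)
  if (!is.null(config$radius) && nrow(result$valency) > 0) {
    tu <- wrapping_time(result$valency)
    out$wrapping_time <- tu
    out$wrapped <- !is.na(tu)
    if (!is.na(tu) &&
        max(result$valency$time) >= tu + 100) {
      out$valency_X <- time_averaged_valency(result$valency, tu)
    } else {
      # fall back to the final quarter of the run when wrapping was not
      # reached (reported as provisional, never as the post-wrap X)
      tail_sel <- result$valency$time >=
        max(result$valency$time) * 0.75
      out$valency_X_final_quarter <-
        mean(result$valency$mean_valency[tail_sel])
    }
  }
  out
}

#' Named experiment presets
#'
#' The standard experiment grids:
#' \describe{
#'   \item{`fig2`}{curvature sweep: radii 7-12 sigma, 50% coverage, 50%
#'     receptors, `epsilon_LR` scaled per sphere so the maximum total
#'     binding energy `N_L * epsilon_LR` matches a 20-epsilon-per-ligand
#'     sphere of radius 7 sigma ([epsilon_for_constant_total_binding()]).}
#'   \item{`fig3`}{coverage x well-depth grid at radius 7 sigma.}
#'   \item{`fig4`}{radius x receptor-fraction grid (radii 7-12, receptor
#'     fractions 20/50/80%), both coupling modes, for the percent-error
#'     comparison.}
#'   \item{`table1`}{radii 7-17 at 50% receptors, pair mode, plus the
#'     valency-rescaled well depths ([rescale_epsilon_by_valency()]).}
#' }
#' `scale` shrinks the geometry for desk-scale smoke runs: radii and
#' membrane edge scale linearly (lipid count quadratically) and the run
#' length scales linearly.  The full-size grids (scale = 1, 10452 or
#' 16296 lipids, 10^4 tau, 5 replicates) reproduce the cluster-scale
#' experiments.
#'
#' @param name One of `"fig2"`, `"fig3"`, `"fig4"`, `"table1"`.
#' @param scale Geometric scale factor in `(0, 1]`. Default 1.
#' @return A list of [experiment_config()] objects.
#' @export
preset_experiment <- function(name = c("fig2", "fig3", "fig4", "table1"),
                              scale = 1) {
  name <- match.arg(name)
  stopifnot(scale > 0, scale <= 1)
  membrane_for <- function(radius) {
    n_full <- if (radius > 12) 16296L else 10452L
    n <- as.integer(2 * round(n_full * scale^2 / 2))
    max(n, 128L)
  }
  sc <- function(r) max(3, r * scale)
  run_tau <- 1e4 * scale
  cfgs <- list()
  if (name == "fig2") {
    e_max <- 20 * n_ligands(sc(7), 0.5)
    for (R in 7:12) {
      Rs <- sc(R)
      cfgs[[length(cfgs) + 1]] <- experiment_config(
        n_lipids = membrane_for(R), receptor_fraction = 0.5,
        radius = Rs, ligand_coverage = 0.5,
        epsilon_LR = epsilon_for_constant_total_binding(
          n_ligands(Rs, 0.5), e_max),
        mode = "pair", run_tau = run_tau,
        label = sprintf("fig2_R%d", R))
    }
  } else if (name == "fig3") {
    for (cov in c(0.1, 0.2, 0.3, 0.4, 0.5)) {
      for (eps in c(5, 10, 15, 20)) {
        cfgs[[length(cfgs) + 1]] <- experiment_config(
          n_lipids = membrane_for(7), receptor_fraction = 0.5,
          radius = sc(7), ligand_coverage = cov, epsilon_LR = eps,
          mode = "pair", run_tau = run_tau,
          label = sprintf("fig3_cov%.1f_eps%g", cov, eps))
      }
    }
  } else if (name == "fig4") {
    for (frac in c(0.2, 0.5, 0.8)) {
      for (R in 7:12) {
        for (mode in c("pair", "bond")) {
          cfgs[[length(cfgs) + 1]] <- experiment_config(
            n_lipids = membrane_for(R), receptor_fraction = frac,
            radius = sc(R), ligand_coverage = 0.5, epsilon_LR = 20,
            mode = mode, run_tau = run_tau,
            label = sprintf("fig4_f%.1f_R%d_%s", frac, R, mode))
        }
      }
    }
  } else {  # table1
    for (R in 7:17) {
      cfgs[[length(cfgs) + 1]] <- experiment_config(
        n_lipids = membrane_for(R), receptor_fraction = 0.5,
        radius = sc(R), ligand_coverage = 0.5, epsilon_LR = 20,
        mode = "pair", run_tau = run_tau,
        label = sprintf("table1_R%d", R))
    }
  }
  cfgs
}
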