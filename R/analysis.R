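# Measurements: ligand valency, wrapping detection, the percent error in
# wrapping time between coupling schemes, the potential-energy valency
# diagnostic, and membrane observables.

#' Per-ligand valency of a configuration
#'
#' Counts the receptors attached to each ligand in the binding graph
#' ([binding_graph()]); the frame mean is total edges / ligand count.
#'
#' @param state A `system_state` containing at least one ligand.
#' @param p An [lr_params()] (its mode selects the binding criterion).
#' @param cutoff Optional pair-mode distance criterion.
#' @return A list: `counts` (integer per ligand, named by bead index)
#'   and `mean`.
#' @export
ligand_valency <- function(state, p, cutoff = lr_binding_cutoff(p)) {
  ligs <- which(state$species == SP_LIGAND)
  if (length(ligs) == 0) stop("configuration has no ligand beads")
  g <- binding_graph(state, p, cutoff)
  counts <- integer(length(ligs))
  names(counts) <- ligs
  if (nrow(g) > 0) {
    tab <- table(factor(g[, 1], levels = ligs))
    counts[] <- as.integer(tab)
  }
  list(counts = counts, mean = sum(counts) / length(ligs))
}

#' Time-averaged ligand valency
#'
#' The unweighted mean of the per-frame mean valencies over the frames
#' recorded at or after `wrap_time + equil`.  The equilibration margin
#' (default 100 tau) ensures the average reflects the fully wrapped
#' final state rather than the wrapping transient.
#'
#' @param valency A data.frame with columns `time` and `mean_valency`
#'   (the `valency` element of a [run_simulation()] result).
#' @param wrap_time Wrapping time (tau), e.g. from [wrapping_time()].
#' @param equil Equilibration margin after wrapping (tau). Default 100.
#' @return The window-averaged valency X.
#' @export
time_averaged_valency <- function(valency, wrap_time, equil = 100) {
  stopifnot(is.data.frame(valency), all(c("time", "mean_valency") %in%
                                        names(valency)))
  if (is.na(wrap_time)) stop("wrap_time is NA (run never wrapped)")
  sel <- valency$time >= wrap_time + equil
  if (!any(sel)) {
    stop("no valency samples at or after wrap_time + equil; extend the run")
  }
  mean(valency$mean_valency[sel])
}

#' Wrapping time from the bound-ligand fraction
#'
#' The nanoparticle counts as completely wrapped at the first sampled
#' time `t` at which the fraction of ligands with at least one bound
#' receptor reaches `threshold` and stays at or above it for the
#' following `hold` tau.  Returns `NA` when the run never wraps.
#'
#' @param valency A data.frame with columns `time` and `bound_fraction`.
#' @param threshold Bound-ligand fraction defining "wrapped". Default 0.95.
#' @param hold Time the threshold must be sustained (tau). Default 10.
#' @return Wrapping time `T_u` (tau), or `NA_real_` if never wrapped.
#' @export
wrapping_time <- function(valency, threshold = 0.95, hold = 10) {
  stopifnot(is.data.frame(valency),
            all(c("time", "bound_fraction") %in% names(valency)))
  t <- valency$time
  ok <- valency$bound_fraction >= threshold
  if (!any(ok)) return(NA_real_)
  cand <- which(ok)
  for (i in cand) {
    inwin <- t >= t[i] & t <= t[i] + hold
    if (all(ok[inwin]) && max(t) >= t[i] + hold) return(t[i])
  }
  NA_real_
}

#' Percent error in wrapping time of the valence-unlimited scheme
#'
#' `100 (T_u^NV - T_u^IV) / T_u^IV`, where `T_u^NV` is the wrapping time
#' with the unrestricted pair potential (no valence limit) and `T_u^IV`
#' the wrapping time with an imposed valence of one.  Positive when the
#' unlimited scheme wraps more slowly.
#'
#' @param Tu_NV Wrapping time(s) of the valence-unlimited system (tau).
#' @param Tu_IV Wrapping time(s) of the imposed-valence system (tau),
#'   strictly positive.
#' @return Percent error (numeric, same length as the inputs).
#' @export
percent_error <- function(Tu_NV, Tu_IV) {
  if (any(!is.finite(Tu_IV)) || any(Tu_IV <= 0)) {
    stop("Tu_IV must be finite and positive")
  }
  100 * (Tu_NV - Tu_IV) / Tu_IV
}

#' Wrapping report over replicates
#'
#' Tabulates per-replicate wrapping times of the two coupling schemes
#' and the percent error of the valence-unlimited one. Unwrapped
#' replicates (`NA`) are kept and flagged, never silently averaged.
#'
#' @param Tu_NV,Tu_IV Equal-length vectors of wrapping times (tau);
#'   `NA` marks an unwrapped replicate.
#' @return A data.frame (replicate, Tu_NV, Tu_IV, wrapped,
#'   percent_error) with the mean and standard deviation of the
#'   per-replicate errors over wrapped pairs as attributes
#'   `mean_percent_error` and `sd_percent_error`.
#' @export
wrapping_report <- function(Tu_NV, Tu_IV) {
  stopifnot(length(Tu_NV) == length(Tu_IV))
  wrapped <- !is.na(Tu_NV) & !is.na(Tu_IV)
  pe <- rep(NA_real_, length(Tu_NV))
  pe[wrapped] <- percent_error(Tu_NV[wrapped], Tu_IV[wrapped])
  out <- data.frame(replicate = seq_along(Tu_NV), Tu_NV = Tu_NV,
                    Tu_IV = Tu_IV, wrapped = wrapped, percent_error = pe)
  attr(out, "mean_percent_error") <- mean(pe[wrapped])
  attr(out, "sd_percent_error") <- stats::sd(pe[wrapped])
  out
}

#' Valency estimate from the potential-energy difference
#'
#' A quick diagnostic for uncontrolled valency: with identical
#' parameters and both systems fully wrapped, the excess (more negative)
#' ligand-receptor energy of the pair-potential system relative to the
#' valence-limited bond system, divided by the per-bond well depth and
#' the ligand count, approximates the extra receptors per ligand.  The
#' `+ 1` accounts for the bond system's own one-bond-per-ligand energy.
#' An approximate scale, not ground truth.
#'
#' @param U_pair Ligand-receptor potential energy of the pair-mode
#'   system (epsilon; negative when bound).
#' @param U_bond Ligand-receptor potential energy of the bond-mode
#'   system (epsilon).
#' @param eps_LR Well depth (epsilon), nonzero.
#' @param N_L Ligand count, positive.
#' @return Estimated pair-mode valency.
#' @export
valency_from_energy <- function(U_pair, U_bond, eps_LR, N_L) {
  if (N_L <= 0) stop("N_L must be positive")
  if (eps_LR == 0) stop("eps_LR must be nonzero")
  (U_bond - U_pair) / (eps_LR * N_L) + 1
}

#' Area per lipid and extrapolated box edge
#'
#' Mean projected box area per upper-leaflet lipid, `Lx Ly / (n/2)`,
#' over a time window of a thermo log, and the lateral edge a membrane
#' of `n_target` lipids would have at that area per lipid.
#'
#' @param thermo A data.frame with columns `time`, `Lx`, `Ly` (the
#'   `thermo` element of a [run_simulation()] result).
#' @param n_lipids Lipid count of the simulated membrane.
#' @param window Time window `c(t0, t1)` (tau); default the final half
#'   of the log.
#' @return A list: `area_per_lipid` (sigma^2) and `edge_for()`, a
#'   function mapping a lipid count to the predicted square box edge
#'   `sqrt(area_per_lipid * n / 2)` (sigma).
#' @export
area_per_lipid <- function(thermo, n_lipids, window = NULL) {
  stopifnot(is.data.frame(thermo),
            all(c("time", "Lx", "Ly") %in% names(thermo)))
  if (is.null(window)) {
    tmax <- max(thermo$time)
    window <- c((min(thermo$time) + tmax) / 2, tmax)
  }
  sel <- thermo$time >= window[1] & thermo$time <= window[2]
  if (!any(sel)) stop("empty averaging window")
  apl <- mean(thermo$Lx[sel] * thermo$Ly[sel]) / (n_lipids / 2)
  list(area_per_lipid = apl,
       edge_for = function(n) sqrt(apl * n / 2))
}

#' Convert reduced units to physical units
#'
#' Uses the calibration of the membrane model against bilayer thickness
#' and lipid diffusion: `sigma = 0.9` nm and `tau = 1` ns by default.
#'
#' @param x Value(s) in reduced units.
#' @param quantity `"length"` (sigma to nm), `"time"` (tau to ns) or
#'   `"area"` (sigma^2 to nm^2).
#' @param sigma_nm,tau_ns The calibration.
#' @return Converted values (nm, ns or nm^2).
#' @export
to_physical_units <- function(x, quantity = c("length", "time", "area"),
                              sigma_nm = 0.9, tau_ns = 1) {
  quantity <- match.arg(quantity)
  switch(quantity,
         length = x * sigma_nm,
         time = x * tau_ns,
         area = x * sigma_nm^2)
}
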