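# The valence-limiting algorithm: explicit ligand-receptor bonds created
# stochastically and ruptured by distance, checked once per timestep.

#' One dynamic-bond update
#'
#' Applies the per-step bond bookkeeping to a configuration:
#' \enumerate{
#'   \item every live bond whose minimum-image length exceeds `r_break`
#'     is removed (rupture runs before formation, so a bond formed at a
#'     length in `(r_break, r_form]` survives until at least the next
#'     step's rupture check);
#'   \item every unbound ligand-receptor pair within `r_form` is visited
#'     in a seeded random order and forms a bond with probability
#'     `p_form`, provided both partners are still below `valence_cap`.
#' }
#' Inside [run_simulation()] the same update runs once per timestep in
#' bond mode; this function exposes it on a static state.
#'
#' @param state A `system_state`.
#' @param p An [lr_params()] with `mode = "bond"`.
#' @param seed Seed for the formation draws and the traversal shuffle.
#' @return A list: `state` (with the updated `lr_bonds` set) and
#'   `events` (data.frame: time, ligand, receptor, event, r).
#' @export
update_bonds <- function(state, p, seed = 1) {
  stopifnot(inherits(state, "system_state"), inherits(p, "lr_params"))
  if (p$mode != "bond") stop("update_bonds requires lr mode = \"bond\"")
  res <- cpp_update_bonds(state, unclass(p), as.double(seed))
  list(state = res$state,
       events = as.data.frame(res$events, stringsAsFactors = FALSE))
}

#' Ligand-receptor binding graph
#'
#' The bipartite graph of ligand-receptor attachments used by every
#' valency measurement.  In bond mode it is the live dynamic-bond set;
#' in pair mode it contains every ligand/receptor-head pair whose
#' minimum-image separation is below the interaction support
#' `r_c + w_c` (about 1.572 sigma for the default coupling), the
#' distance beyond which the pair potential is exactly zero.
#'
#' @param state A `system_state`.
#' @param p An [lr_params()]; its `mode` selects the criterion.
#' @param cutoff Pair-mode distance criterion; defaults to
#'   [lr_binding_cutoff()] of `p`.
#' @return Two-column integer matrix `(ligand, receptor)` of bead
#'   indices; zero rows when nothing is bound.
#' @export
binding_graph <- function(state, p, cutoff = lr_binding_cutoff(p)) {
  stopifnot(inherits(state, "system_state"), inherits(p, "lr_params"))
  if (p$mode == "bond") {
    g <- state$lr_bonds
    colnames(g) <- NULL
    return(g)
  }
  pairs <- neighbor_pairs(state, cutoff)
  if (nrow(pairs) == 0) return(matrix(integer(), 0, 2))
  s1 <- state$species[pairs[, 1]]
  s2 <- state$species[pairs[, 2]]
  lr <- s1 == SP_LIGAND & s2 == SP_RECEPTOR
  rl <- s1 == SP_RECEPTOR & s2 == SP_LIGAND
  g <- rbind(pairs[lr, , drop = FALSE],
             pairs[rl, 2:1, drop = FALSE])
  dimnames(g) <- NULL
  g
}
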