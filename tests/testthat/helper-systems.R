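# Fixtures and independent oracles shared across the suite.  Everything is
# generated in code; the oracles deliberately use naive O(N^2) scans and the
# plain R closed forms, never the engine's own machinery.

# minimal bare system (no topology) from a position matrix
bare_state <- function(pos, species, box, vel = NULL, rigid = list()) {
  n <- nrow(pos)
  memwrap:::new_system_state(
    pos = pos,
    vel = if (is.null(vel)) matrix(0, n, 3) else vel,
    species = as.integer(species), mass = rep(1, n),
    bonds = matrix(integer(), 0, 2), bond_type = integer(),
    angles = matrix(integer(), 0, 3), box = box, rigid_bodies = rigid)
}

# minimum-image distance, naive
mi_dist <- function(a, b, box) {
  d <- a - b
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

# O(N^2) neighbour-pair oracle
bf_pairs <- function(pos, box, cutoff) {
  n <- nrow(pos)
  out <- matrix(integer(), 0, 2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (mi_dist(pos[i, ], pos[j, ], box) < cutoff) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

# O(N_L x N_R) binding-graph oracle (pair criterion)
bf_binding_graph <- function(state, cutoff) {
  ligs <- which(state$species == 5L)
  recs <- which(state$species == 3L)
  out <- matrix(integer(), 0, 2)
  for (l in ligs) {
    for (r in recs) {
      if (mi_dist(state$pos[l, ], state$pos[r, ], state$box) < cutoff) {
        out <- rbind(out, c(l, r))
      }
    }
  }
  out
}

# canonical ordering so edge sets can be compared
sort_pairs <- function(m) {
  if (nrow(m) == 0) return(m)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# central-difference derivative
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# full potential energy of a small state computed in plain R from the
# closed-form module functions (independent of the compiled engine)
r_potential_energy <- function(state, ff) {
  n <- nrow(state$pos)
  box <- state$box
  bonded <- matrix(FALSE, n, n)
  if (nrow(state$bonds) > 0) {
    for (k in seq_len(nrow(state$bonds))) {
      i <- state$bonds[k, 1]; j <- state$bonds[k, 2]
      bonded[i, j] <- bonded[j, i] <- TRUE
    }
  }
  rigid <- unlist(state$rigid_bodies)
  u <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (bonded[i, j]) next
      if (i %in% rigid && j %in% rigid) next
      r <- mi_dist(state$pos[i, ], state$pos[j, ], box)
      si <- state$species[i]; sj <- state$species[j]
      u <- u + wca_energy(r, wca_params(b = ff$b[si, sj]))
      if (si == 2L && sj == 2L) {
        u <- u + cosine_attraction_energy(r, ff$tail_cos)
      }
      lr_pair <- (si == 5L && sj == 3L) || (si == 3L && sj == 5L)
      if (lr_pair && !is.null(ff$lr) && ff$lr$mode == "pair") {
        u <- u + ligand_receptor_energy(r, ff$lr)
      }
    }
  }
  if (nrow(state$bonds) > 0) {
    for (k in seq_len(nrow(state$bonds))) {
      r <- mi_dist(state$pos[state$bonds[k, 1], ],
                   state$pos[state$bonds[k, 2], ], box)
      u <- u + fene_energy(r, ff$fene[[state$bond_type[k]]])
    }
  }
  if (nrow(state$angles) > 0) {
    for (k in seq_len(nrow(state$angles))) {
      a <- state$pos[state$angles[k, 1], ]
      b <- state$pos[state$angles[k, 2], ]
      cc <- state$pos[state$angles[k, 3], ]
      d1 <- a - b; d1 <- d1 - box * round(d1 / box)
      d2 <- cc - b; d2 <- d2 - box * round(d2 / box)
      ct <- sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2))
      u <- u + angle_energy(acos(max(-1, min(1, ct))), ff$angle)
    }
  }
  if (!is.null(ff$lr) && ff$lr$mode == "bond" && nrow(state$lr_bonds) > 0) {
    for (k in seq_len(nrow(state$lr_bonds))) {
      r <- mi_dist(state$pos[state$lr_bonds[k, 1], ],
                   state$pos[state$lr_bonds[k, 2], ], box)
      u <- u + ligand_receptor_energy(r, ff$lr)
    }
  }
  u
}

# small equilibrated-ish membrane patch for engine tests (cached per session)
small_patch <- local({
  cache <- list()
  function(n_lipids = 50, seed = 3) {
    key <- paste(n_lipids, seed)
    if (is.null(cache[[key]])) {
      m <- build_membrane(n_lipids, receptor_fraction = 0, Lz = 30,
                          seed = seed)
      m <- thermalize_velocities(m, 1, seed)
      cache[[key]] <<- m
    }
    cache[[key]]
  }
})
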