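# Deterministic, seeded construction of bilayer patches and
# ligand-decorated nanospheres, plus the epsilon_LR scaling rules.

#' @keywords internal
species_levels <- c("head", "tail", "receptor_head", "np_surface", "ligand")

SP_HEAD <- 1L
SP_TAIL <- 2L
SP_RECEPTOR <- 3L
SP_NPSURF <- 4L
SP_LIGAND <- 5L

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

new_system_state <- function(pos, vel, species, mass, bonds, bond_type,
                             angles, box, rigid_bodies = list(),
                             lr_bonds = matrix(integer(), 0, 2),
                             time = 0) {
  stopifnot(is.matrix(pos), ncol(pos) == 3,
            nrow(vel) == nrow(pos), length(species) == nrow(pos))
  dimnames(pos) <- NULL
  dimnames(vel) <- NULL
  structure(list(pos = pos, vel = vel, species = as.integer(species),
                 mass = mass, bonds = bonds, bond_type = as.integer(bond_type),
                 angles = angles, box = box, rigid_bodies = rigid_bodies,
                 lr_bonds = lr_bonds, time = time),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cnt <- table(factor(species_levels[x$species], levels = species_levels))
  cat("system_state:", nrow(x$pos), "beads |",
      nrow(x$bonds), "bonds |", nrow(x$angles), "angles |",
      nrow(x$lr_bonds), "live LR bonds\n")
  cat("  box:", sprintf("%.2f x %.2f x %.2f sigma", x$box[1], x$box[2],
                        x$box[3]), "| time:", x$time, "tau\n")
  cat("  species:", paste(names(cnt), cnt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Expected receptor count for a membrane
#'
#' Receptors are drawn from the nanoparticle-facing (upper) leaflet; the
#' count is `floor(receptor_fraction * n_lipids / 2)` under the default
#' per-leaflet reading, or `floor(receptor_fraction * n_lipids)` under
#' the whole-membrane reading.
#'
#' @param n_lipids Total lipid count (both leaflets).
#' @param receptor_fraction Fraction in `[0, 1]`.
#' @param basis `"leaflet"` (default) or `"membrane"`.
#' @return Integer receptor count.
#' @export
#' @examples
#' n_receptors(10452, 0.20)  # 1045
n_receptors <- function(n_lipids, receptor_fraction, basis = c("leaflet", "membrane")) {
  basis <- match.arg(basis)
  stopifnot(receptor_fraction >= 0, receptor_fraction <= 1)
  n <- switch(basis,
              leaflet = floor(receptor_fraction * n_lipids / 2),
              membrane = floor(receptor_fraction * n_lipids))
  as.integer(n)
}

#' Surface-bead and ligand counts for a nanosphere
#'
#' A sphere of radius `R` carries `floor(4 pi R^2)` surface beads (about
#' one per sigma^2, so neighbouring beads sit roughly 1 sigma apart), of
#' which `floor(coverage * N_surface)` are ligands.
#'
#' @param radius Sphere radius (sigma).
#' @param coverage Ligand coverage fraction in `[0, 1]`.
#' @return Integer count.
#' @export
#' @examples
#' n_surface_beads(12)   # 1809
#' n_ligands(12, 0.5)    # 904
n_surface_beads <- function(radius) {
  stopifnot(radius > 0)
  as.integer(floor(4 * pi * radius^2))
}

#' @rdname n_surface_beads
#' @export
n_ligands <- function(radius, coverage) {
  stopifnot(coverage >= 0, coverage <= 1)
  as.integer(floor(coverage * n_surface_beads(radius)))
}

# Factor n into (nx, ny) with nx * ny == n, as close to square as possible.
closest_factor_pair <- function(n) {
  for (nx in floor(sqrt(n)):1) {
    if (n %% nx == 0) return(c(nx, n %/% nx))
  }
  stop("cannot factor lattice")  # unreachable: nx = 1 always divides
}

#' Build a bilayer membrane patch
#'
#' Places `n_lipids / 2` three-bead lipids per leaflet on a rectangular
#' lattice (as close to square as the lipid count allows) at the given
#' initial area per lipid, tails pointing inward, heads outward.  Each
#' lipid contributes two FENE bonds (head-tail of type 1, tail-tail of
#' type 2) and one 180-degree harmonic angle.  Receptors are a seeded
#' uniform sample of the upper (nanoparticle-facing) leaflet; they differ
#' from plain lipids only by the species label on the head bead.
#'
#' The lattice starts slightly expanded (default 1.2 sigma^2 per lipid);
#' the zero-tension lateral barostat compresses it to its equilibrium
#' area during equilibration.
#'
#' @param n_lipids Total lipid count; must be even.
#' @param receptor_fraction Fraction of the upper leaflet's lipids
#'   carrying a receptor head (see [n_receptors()]).
#' @param area_per_lipid Initial lattice area per lipid (sigma^2).
#' @param Lz Box height (sigma); large enough that the membrane never
#'   sees its periodic image. Default 60.
#' @param seed Seed for the receptor assignment.
#' @param receptor_basis Interpretation of `receptor_fraction`; see
#'   [n_receptors()].
#' @return A `system_state` with the membrane centred at z = 0.
#' @export
#' @examples
#' m <- build_membrane(128, receptor_fraction = 0.5, seed = 1)
#' sum(m$species == 3L)  # 32 receptor heads
build_membrane <- function(n_lipids, receptor_fraction = 0.5,
                           area_per_lipid = 1.2, Lz = 60, seed = 1,
                           receptor_basis = c("leaflet", "membrane")) {
  receptor_basis <- match.arg(receptor_basis)
  if (n_lipids <= 0 || n_lipids %% 2 != 0) {
    stop("n_lipids must be a positive even number")
  }
  stopifnot(receptor_fraction >= 0, receptor_fraction <= 1,
            area_per_lipid > 0)
  nper <- n_lipids %/% 2
  nf <- closest_factor_pair(nper)
  nx <- nf[2]; ny <- nf[1]
  a <- sqrt(area_per_lipid)
  Lx <- nx * a; Ly <- ny * a
  if (Lz < 20) stop("Lz too small for a non-interacting periodic image")

  ix <- rep(seq_len(nx) - 1, times = ny)
  iy <- rep(seq_len(ny) - 1, each = nx)
  xs <- (ix + 0.5) * a
  ys <- (iy + 0.5) * a

  # bead z offsets per leaflet: head outermost, tails toward mid-plane
  zs_up <- c(2.4, 1.45, 0.5)
  zs_dn <- -zs_up
  n_beads <- 3L * n_lipids
  pos <- matrix(0, n_beads, 3)
  species <- integer(n_beads)
  for (leaf in 1:2) {
    zoff <- if (leaf == 1) zs_up else zs_dn
    base <- (leaf - 1L) * 3L * nper
    idx <- base + seq.int(1L, 3L * nper, by = 3L)
    for (k in 1:3) {
      pos[idx + (k - 1L), 1] <- xs
      pos[idx + (k - 1L), 2] <- ys
      pos[idx + (k - 1L), 3] <- zoff[k] + Lz / 2
    }
    species[idx] <- SP_HEAD
    species[idx + 1L] <- SP_TAIL
    species[idx + 2L] <- SP_TAIL
  }

  nrec <- n_receptors(n_lipids, receptor_fraction, receptor_basis)
  if (nrec > nper) {
    stop("receptor count exceeds the upper-leaflet lipid count")
  }
  if (nrec > 0) {
    rec_lipids <- with_seed(seed, sort(sample.int(nper, nrec)))
    species[(rec_lipids - 1L) * 3L + 1L] <- SP_RECEPTOR
  }

  first <- seq.int(1L, n_beads, by = 3L)
  bonds <- rbind(cbind(first, first + 1L), cbind(first + 1L, first + 2L))
  bond_type <- c(rep(1L, n_lipids), rep(2L, n_lipids))
  ord <- order(rep(seq_len(n_lipids), 2))
  bonds <- bonds[ord, , drop = FALSE]
  bond_type <- bond_type[ord]
  angles <- cbind(first, first + 1L, first + 2L)
  dimnames(bonds) <- NULL; dimnames(angles) <- NULL

  new_system_state(pos = pos, vel = matrix(0, n_beads, 3),
                   species = species, mass = rep(1, n_beads),
                   bonds = bonds, bond_type = bond_type, angles = angles,
                   box = c(Lx, Ly, Lz))
}

#' Build a ligand-decorated rigid nanosphere
#'
#' Surface beads are placed on a Fibonacci (golden-angle) lattice of
#' radius `R`, which yields a deterministic, nearly uniform covering with
#' neighbour spacing close to 1 sigma when `N = floor(4 pi R^2)`.
#' Ligands are a seeded uniform sample of the surface beads.  All beads
#' belong to a single rigid body.
#'
#' @param radius Sphere radius (sigma); must give at least 4 surface beads.
#' @param ligand_coverage Fraction of surface beads that are ligands.
#' @param seed Seed for the ligand assignment.
#' @param center Sphere centre, length-3 numeric. Default origin.
#' @return A `system_state` fragment (no bonds or angles; one rigid body).
#' @export
#' @examples
#' np <- build_nanoparticle(7, ligand_coverage = 0.5, seed = 1)
#' sum(np$species == 5L)  # floor(0.5 * floor(4 * pi * 49)) = 307 ligands
build_nanoparticle <- function(radius, ligand_coverage = 0.5, seed = 1,
                               center = c(0, 0, 0)) {
  stopifnot(radius > 0, ligand_coverage >= 0, ligand_coverage <= 1)
  n <- n_surface_beads(radius)
  if (n < 4) stop("radius too small: fewer than 4 surface beads")
  i <- seq_len(n) - 1
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * (i + 0.5) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  phi <- golden * i
  pos <- radius * cbind(rho * cos(phi), rho * sin(phi), z)
  pos <- sweep(pos, 2, center, "+")

  species <- rep(SP_NPSURF, n)
  nl <- n_ligands(radius, ligand_coverage)
  if (nl > 0) {
    lig <- with_seed(seed, sort(sample.int(n, nl)))
    species[lig] <- SP_LIGAND
  }
  new_system_state(pos = pos, vel = matrix(0, n, 3), species = species,
                   mass = rep(1, n),
                   bonds = matrix(integer(), 0, 2), bond_type = integer(),
                   angles = matrix(integer(), 0, 3),
                   box = c(2 * radius + 4, 2 * radius + 4, 2 * radius + 4),
                   rigid_bodies = list(seq_len(n)))
}

#' Combine a membrane patch and a nanoparticle into one system
#'
#' The nanoparticle is centred laterally and placed so that its lowest
#' surface bead sits `gap` sigma above the upper-leaflet head plane.
#' The membrane's box is kept; it must be tall and wide enough to hold
#' the sphere.
#'
#' @param membrane A membrane `system_state` from [build_membrane()].
#' @param nanoparticle A `system_state` from [build_nanoparticle()].
#' @param gap Initial vertical clearance (sigma). Default 3.
#' @return A combined `system_state`.
#' @export
assemble_system <- function(membrane, nanoparticle, gap = 3) {
  stopifnot(inherits(membrane, "system_state"),
            inherits(nanoparticle, "system_state"))
  nm <- nrow(membrane$pos)
  np_pos <- nanoparticle$pos
  ctr <- colMeans(np_pos)
  radius <- sqrt(max(rowSums(sweep(np_pos, 2, ctr)^2)))
  top_head <- max(membrane$pos[membrane$species %in% c(SP_HEAD, SP_RECEPTOR), 3])
  target <- c(membrane$box[1] / 2, membrane$box[2] / 2,
              top_head + gap + radius)
  np_pos <- sweep(np_pos, 2, target - ctr, "+")
  if (max(np_pos[, 3]) > membrane$box[3] - 2) {
    stop("box height too small for the nanoparticle placement")
  }
  if (2 * radius > min(membrane$box[1:2])) {
    stop("membrane patch narrower than the nanoparticle diameter")
  }
  new_system_state(
    pos = rbind(membrane$pos, np_pos),
    vel = rbind(membrane$vel, nanoparticle$vel),
    species = c(membrane$species, nanoparticle$species),
    mass = c(membrane$mass, nanoparticle$mass),
    bonds = membrane$bonds, bond_type = membrane$bond_type,
    angles = membrane$angles, box = membrane$box,
    rigid_bodies = lapply(nanoparticle$rigid_bodies, function(b) b + nm),
    time = membrane$time)
}

#' Scale the per-ligand well depth to hold total binding energy constant
#'
#' For curvature sweeps the interaction strength is scaled so that the
#' maximum total binding energy `E_max = N_L * epsilon_LR` is the same
#' for every sphere regardless of its ligand count: larger spheres carry
#' more ligands, each with a proportionally weaker well.
#'
#' @param N_L Ligand count (> 0).
#' @param E_max Target total binding energy (epsilon units).
#' @return `epsilon_LR = E_max / N_L`.
#' @export
epsilon_for_constant_total_binding <- function(N_L, E_max) {
  if (N_L <= 0) stop("N_L must be positive")
  E_max / N_L
}

#' Rescale the well depth by a measured valency
#'
#' Dividing the original well depth by the measured pair-mode valency
#' attempts to recover an effective one-bond-per-ligand energy; it
#' reduces, but does not remove, the valency artifact.
#'
#' @param eps_o Original well depth (epsilon units, typically 20).
#' @param X Measured time-averaged valency (> 0).
#' @return `eps_o / X`.
#' @export
rescale_epsilon_by_valency <- function(eps_o, X) {
  if (any(X <= 0)) stop("valency X must be positive")
  eps_o / X
}

#' Cooke-Deserno force field with ligand-receptor coupling
#'
#' Assembles every interaction of the model:
#' \itemize{
#'   \item WCA excluded volume between all bead pairs, with
#'     `b = 0.95` sigma everywhere except tail-tail (`b = 1` sigma);
#'   \item broad cosine attraction (depth 1 epsilon, onset `2^(1/6)`
#'     sigma, width `w_c`) between tail beads only;
#'   \item FENE bonds (type 1 head-tail with `b = 0.95`, type 2
#'     tail-tail with `b = 1`) and harmonic 180-degree angles within
#'     each lipid;
#'   \item the ligand-receptor coupling of [lr_params()] between ligand
#'     beads and receptor heads, as a pair potential or a dynamic bond
#'     depending on `lr$mode`.
#' }
#'
#' @param w_c Tail-tail attraction width (sigma). Default 1.5, the fluid
#'   phase at kT = 1 epsilon.
#' @param lr An [lr_params()] object, or `NULL` for a membrane-only
#'   system.
#' @param b_head WCA length for pairs involving head, receptor-head or
#'   nanoparticle beads. Default 0.95.
#' @param b_tail WCA length for tail-tail pairs. Default 1.
#' @return An object of class `forcefield`.
#' @export
forcefield <- function(w_c = 1.5, lr = lr_params(), b_head = 0.95,
                       b_tail = 1) {
  if (!is.null(lr)) stopifnot(inherits(lr, "lr_params"))
  nsp <- length(species_levels)
  bmat <- matrix(b_head, nsp, nsp,
                 dimnames = list(species_levels, species_levels))
  bmat["tail", "tail"] <- b_tail
  structure(list(
    b = bmat,
    tail_cos = cosine_params(epsilon = 1, r_c = 2^(1 / 6) * b_tail,
                             w_c = w_c),
    fene = list(fene_params(wca = wca_params(b = b_head)),
                fene_params(wca = wca_params(b = b_tail))),
    angle = angle_params(),
    lr = lr
  ), class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat("Cooke-Deserno force field: w_c =", x$tail_cos$w_c, "sigma\n")
  if (is.null(x$lr)) {
    cat("  no ligand-receptor coupling\n")
  } else {
    cat(sprintf("  LR coupling: mode=%s, eps_LR=%g, support=%.3f sigma\n",
                x$lr$mode, x$lr$epsilon, lr_binding_cutoff(x$lr)))
  }
  invisible(x)
}
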