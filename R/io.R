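# Interchange with the standard particle-simulation text formats, plus a
# plain-text checkpoint for restartable runs.

#' Write a tabulated potential file
#'
#' Writes a potential table (e.g. from [tabulate_bond_potential()]) in
#' the engine-standard tabulated pair/bond style: a keyword header, the
#' point count, and `index r energy force` rows.
#'
#' @param tab A data.frame with columns `r`, `U`, `F`.
#' @param path Output file.
#' @param keyword Section keyword. Default `"LR_BOND"`.
#' @return `path`, invisibly.
#' @export
write_potential_table <- function(tab, path, keyword = "LR_BOND") {
  stopifnot(all(c("r", "U", "F") %in% names(tab)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ligand-receptor cosine-squared attraction (reduced units)",
               "", keyword, sprintf("N %d", nrow(tab)), ""), con)
  writeLines(sprintf("%d %.10g %.10g %.10g", seq_len(nrow(tab)),
                     tab$r, tab$U, tab$F), con)
  invisible(path)
}

#' Read a tabulated potential file
#'
#' @param path File written by [write_potential_table()] (or any
#'   single-section engine-standard table).
#' @return A data.frame with columns `r`, `U`, `F`.
#' @export
read_potential_table <- function(path) {
  lines <- readLines(path)
  nline <- grep("^N ", lines)[1]
  n <- as.integer(sub("^N +", "", lines[nline]))
  rows <- lines[grep("^[0-9]+ ", lines)]
  stopifnot(length(rows) == n)
  m <- do.call(rbind, lapply(strsplit(rows, " +"), as.numeric))
  data.frame(r = m[, 2], U = m[, 3], F = m[, 4])
}

#' Write a system as an engine-standard data file
#'
#' Full topology (atoms with molecule ids, masses, FENE bonds, angles)
#' in the `atom_style angle` data-file layout, so a built system can be
#' run in the reference MD engine as well.
#'
#' @param state A `system_state`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(state, path) {
  stopifnot(inherits(state, "system_state"))
  n <- nrow(state$pos)
  nb <- nrow(state$bonds)
  na <- nrow(state$angles)
  # molecule id: one per lipid (3 consecutive beads), one for the body
  mol <- integer(n)
  if (na > 0) {
    for (k in seq_len(na)) mol[state$angles[k, ]] <- k
  }
  rigid <- unlist(state$rigid_bodies)
  if (length(rigid)) mol[rigid] <- max(mol) + 1L
  mol[mol == 0] <- max(mol) + seq_len(sum(mol == 0))

  con <- file(path, "w")
  on.exit(close(con))
  writeLines("coarse-grained membrane + nanoparticle system", con)
  writeLines("", con)
  writeLines(c(sprintf("%d atoms", n),
               sprintf("%d bonds", nb),
               sprintf("%d angles", na),
               sprintf("%d atom types", length(species_levels)),
               "2 bond types",
               "1 angle types", ""), con)
  writeLines(c(sprintf("0.0 %.10g xlo xhi", state$box[1]),
               sprintf("0.0 %.10g ylo yhi", state$box[2]),
               sprintf("0.0 %.10g zlo zhi", state$box[3]), ""), con)
  writeLines(c("Masses", "",
               sprintf("%d 1.0", seq_along(species_levels)), ""), con)
  writeLines(c("Atoms # angle", ""), con)
  writeLines(sprintf("%d %d %d %.10g %.10g %.10g", seq_len(n), mol,
                     state$species, state$pos[, 1], state$pos[, 2],
                     state$pos[, 3]), con)
  if (nb > 0) {
    writeLines(c("", "Bonds", ""), con)
    writeLines(sprintf("%d %d %d %d", seq_len(nb), state$bond_type,
                       state$bonds[, 1], state$bonds[, 2]), con)
  }
  if (na > 0) {
    writeLines(c("", "Angles", ""), con)
    writeLines(sprintf("%d 1 %d %d %d", seq_len(na), state$angles[, 1],
                       state$angles[, 2], state$angles[, 3]), con)
  }
  writeLines(c("", "Velocities", ""), con)
  writeLines(sprintf("%d %.10g %.10g %.10g", seq_len(n), state$vel[, 1],
                     state$vel[, 2], state$vel[, 3]), con)
  invisible(path)
}

#' Read an engine-standard data file
#'
#' Parses the `atom_style angle` layout written by
#' [write_lammps_data()]: box, species, positions, velocities, bonds and
#' angles.  Rigid-body membership and dynamic bonds are not part of the
#' format; use checkpoints ([write_checkpoint()]) to round-trip those.
#'
#' @param path Data file.
#' @return A `system_state` (without rigid bodies or live LR bonds).
#' @export
read_lammps_data <- function(path) {
  lines <- readLines(path)
  grab <- function(pattern) {
    as.numeric(strsplit(trimws(grep(pattern, lines, value = TRUE)[1]),
                        " +")[[1]][1])
  }
  n <- grab(" atoms$")
  nb <- grab(" bonds$")
  na <- grab(" angles$")
  getbound <- function(tag) {
    v <- as.numeric(strsplit(trimws(grep(tag, lines, value = TRUE)[1]),
                             " +")[[1]][1:2])
    v[2] - v[1]
  }
  box <- c(getbound("xlo xhi"), getbound("ylo yhi"), getbound("zlo zhi"))

  section <- function(name, ncol, nrows) {
    i <- grep(paste0("^", name), lines)[1]
    if (is.na(i) || nrows == 0) return(matrix(numeric(), 0, ncol))
    rows <- lines[(i + 2):(i + 1 + nrows)]
    do.call(rbind, lapply(strsplit(trimws(rows), " +"),
                          function(v) as.numeric(v[seq_len(ncol)])))
  }
  atoms <- section("Atoms", 6, n)
  atoms <- atoms[order(atoms[, 1]), , drop = FALSE]
  vels <- section("Velocities", 4, n)
  vels <- vels[order(vels[, 1]), , drop = FALSE]
  bonds <- section("Bonds", 4, nb)
  angs <- section("Angles", 5, na)
  new_system_state(
    pos = atoms[, 4:6, drop = FALSE],
    vel = if (nrow(vels)) vels[, 2:4, drop = FALSE] else matrix(0, n, 3),
    species = as.integer(atoms[, 3]),
    mass = rep(1, n),
    bonds = if (nb > 0) matrix(as.integer(bonds[, 3:4]), ncol = 2)
            else matrix(integer(), 0, 2),
    bond_type = if (nb > 0) as.integer(bonds[, 2]) else integer(),
    angles = if (na > 0) matrix(as.integer(angs[, 3:5]), ncol = 3)
             else matrix(integer(), 0, 3),
    box = box)
}

#' Write an XYZ trajectory or snapshot
#'
#' Standard extended-XYZ text: bead count, a comment line carrying time
#' and box, then `label x y z` rows.  Species labels are H (head),
#' T (tail), R (receptor head), N (nanoparticle surface), L (ligand).
#'
#' @param x A `system_state`, or a `sim_result` whose trajectory was
#'   kept (`keep_trajectory = TRUE`).
#' @param path Output file; frames are appended in order.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  labels <- c("H", "T", "R", "N", "L")
  con <- file(path, "w")
  on.exit(close(con))
  put_frame <- function(pos, species, time, box) {
    writeLines(as.character(nrow(pos)), con)
    writeLines(sprintf("time=%.4f box=%.6g,%.6g,%.6g", time,
                       box[1], box[2], box[3]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", labels[species],
                       pos[, 1], pos[, 2], pos[, 3]), con)
  }
  if (inherits(x, "system_state")) {
    put_frame(x$pos, x$species, x$time, x$box)
  } else if (inherits(x, "sim_result")) {
    if (is.null(x$trajectory)) stop("sim_result holds no trajectory frames")
    tr <- x$trajectory
    for (k in seq_along(tr$frames)) {
      put_frame(tr$frames[[k]], x$state$species, tr$time[k],
                c(tr$Lx[k], tr$Ly[k], x$state$box[3]))
    }
  } else {
    stop("x must be a system_state or sim_result")
  }
  invisible(path)
}

#' Write a trajectory in the engine-standard dump text format
#'
#' @param result A `sim_result` with stored frames.
#' @param path Output file.
#' @param dt Timestep used, to convert frame times to step numbers.
#' @return `path`, invisibly.
#' @export
write_dump <- function(result, path, dt = 0.01) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$trajectory)) stop("sim_result holds no trajectory frames")
  tr <- result$trajectory
  species <- result$state$species
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(tr$frames)) {
    pos <- tr$frames[[k]]
    writeLines(c("ITEM: TIMESTEP", sprintf("%d", round(tr$time[k] / dt)),
                 "ITEM: NUMBER OF ATOMS", sprintf("%d", nrow(pos)),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0.0 %.8g", tr$Lx[k]),
                 sprintf("0.0 %.8g", tr$Ly[k]),
                 sprintf("0.0 %.8g", result$state$box[3]),
                 "ITEM: ATOMS id type x y z"), con)
    writeLines(sprintf("%d %d %.6f %.6f %.6f", seq_len(nrow(pos)), species,
                       pos[, 1], pos[, 2], pos[, 3]), con)
  }
  invisible(path)
}

#' Write the bond-event log
#'
#' Tab-separated table of dynamic-bond events: time, ligand, receptor,
#' event (`formed`/`broken`), separation at the event.
#'
#' @param events The `events` data.frame of a [run_simulation()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bond_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Plain-text checkpoint of a full system state
#'
#' Round-trips everything a restart needs: box, time, species, masses,
#' positions, velocities, topology, rigid-body membership and the live
#' dynamic-bond set.  Continuation runs draw their thermostat noise from
#' the seed given to the next [run_simulation()] call; record that seed
#' alongside the checkpoint for full provenance.
#'
#' @param state A `system_state`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "system_state"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(state$pos)
  writeLines(c("# memwrap checkpoint v1",
               sprintf("time %.12g", state$time),
               sprintf("box %.12g %.12g %.12g", state$box[1], state$box[2],
                       state$box[3]),
               sprintf("natoms %d", n)), con)
  writeLines("ATOMS id species mass x y z vx vy vz", con)
  writeLines(sprintf("%d %d %.12g %.12g %.12g %.12g %.12g %.12g %.12g",
                     seq_len(n), state$species, state$mass,
                     state$pos[, 1], state$pos[, 2], state$pos[, 3],
                     state$vel[, 1], state$vel[, 2], state$vel[, 3]), con)
  writeLines(sprintf("BONDS %d", nrow(state$bonds)), con)
  if (nrow(state$bonds)) {
    writeLines(sprintf("%d %d %d", state$bond_type, state$bonds[, 1],
                       state$bonds[, 2]), con)
  }
  writeLines(sprintf("ANGLES %d", nrow(state$angles)), con)
  if (nrow(state$angles)) {
    writeLines(sprintf("%d %d %d", state$angles[, 1], state$angles[, 2],
                       state$angles[, 3]), con)
  }
  rigid <- if (length(state$rigid_bodies)) state$rigid_bodies[[1]] else integer()
  writeLines(sprintf("RIGID %d", length(rigid)), con)
  if (length(rigid)) writeLines(paste(rigid, collapse = " "), con)
  writeLines(sprintf("LRBONDS %d", nrow(state$lr_bonds)), con)
  if (nrow(state$lr_bonds)) {
    writeLines(sprintf("%d %d", state$lr_bonds[, 1], state$lr_bonds[, 2]), con)
  }
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  lines <- readLines(path)
  val <- function(key) {
    as.numeric(strsplit(grep(paste0("^", key, " "), lines,
                             value = TRUE)[1], " +")[[1]][-1])
  }
  time <- val("time")
  box <- val("box")
  n <- as.integer(val("natoms"))
  i0 <- grep("^ATOMS ", lines)[1]
  at <- do.call(rbind, lapply(strsplit(lines[(i0 + 1):(i0 + n)], " +"),
                              as.numeric))
  i <- i0 + n + 1
  nb <- as.integer(strsplit(lines[i], " +")[[1]][2])
  bonds <- matrix(integer(), 0, 2); btype <- integer()
  if (nb > 0) {
    bm <- do.call(rbind, lapply(strsplit(lines[(i + 1):(i + nb)], " +"),
                                as.numeric))
    btype <- as.integer(bm[, 1])
    bonds <- matrix(as.integer(bm[, 2:3]), ncol = 2)
  }
  i <- i + nb + 1
  na <- as.integer(strsplit(lines[i], " +")[[1]][2])
  angles <- matrix(integer(), 0, 3)
  if (na > 0) {
    angles <- matrix(as.integer(do.call(rbind, lapply(
      strsplit(lines[(i + 1):(i + na)], " +"), as.numeric))), ncol = 3)
  }
  i <- i + na + 1
  nr <- as.integer(strsplit(lines[i], " +")[[1]][2])
  rigid <- list()
  if (nr > 0) {
    rigid <- list(as.integer(strsplit(lines[i + 1], " +")[[1]]))
    i <- i + 1
  }
  i <- i + 1
  nl <- as.integer(strsplit(lines[i], " +")[[1]][2])
  lrb <- matrix(integer(), 0, 2)
  if (nl > 0) {
    lrb <- matrix(as.integer(do.call(rbind, lapply(
      strsplit(lines[(i + 1):(i + nl)], " +"), as.numeric))), ncol = 2)
  }
  new_system_state(pos = at[, 4:6, drop = FALSE],
                   vel = at[, 7:9, drop = FALSE],
                   species = as.integer(at[, 2]), mass = at[, 3],
                   bonds = bonds, bond_type = btype, angles = angles,
                   box = box, rigid_bodies = rigid, lr_bonds = lrb,
                   time = time)
}

#' Write a machine-readable run summary
#'
#' JSON key-value document for downstream tooling: whatever scalar
#' observables the caller assembles (valency X, wrapping times, percent
#' error, area per lipid, mean temperature, seeds, config hash, ...).
#'
#' @param summary A named list of scalars.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
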