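# Closed-form potentials of the three-bead lipid model and the
# ligand-receptor coupling.  All quantities are in reduced Lennard-Jones
# units: energy epsilon, length sigma, time tau, mass m.

#' Weeks-Chandler-Andersen (WCA) repulsion parameters
#'
#' The WCA potential is the Lennard-Jones potential truncated at its
#' minimum `r_c = 2^(1/6) b` and shifted up by `epsilon`, leaving a purely
#' repulsive excluded-volume interaction that is continuous (with
#' continuous force) at the cutoff.
#'
#' @param epsilon Well depth of the underlying Lennard-Jones potential
#'   (energy, epsilon units). Default 1.
#' @param b Length scale setting the bead diameter (sigma units). The lipid
#'   model uses `b = 0.95` for head-head and head-tail pairs and `b = 1`
#'   for tail-tail pairs.
#' @return An object of class `wca_params` with fields `epsilon`, `b` and
#'   the derived cutoff `r_c = 2^(1/6) b`.
#' @export
#' @examples
#' p <- wca_params(b = 0.95)
#' wca_energy(p$r_c, p)   # exactly zero at the cutoff
wca_params <- function(epsilon = 1, b = 1) {
  stopifnot(epsilon >= 0, b > 0)
  structure(list(epsilon = epsilon, b = b, r_c = 2^(1 / 6) * b),
            class = "wca_params")
}

#' WCA energy and force
#'
#' `wca_energy()` evaluates `4 eps [(b/r)^12 - (b/r)^6] + eps` for
#' `r < r_c` and 0 beyond; `wca_force()` is the central force `-dU/dr`
#' (positive = repulsive).
#'
#' @param r Separation(s), sigma units; must be strictly positive.
#' @param p A [wca_params()] object.
#' @return Numeric vector of energies (epsilon units) or forces
#'   (epsilon/sigma units).
#' @export
wca_energy <- function(r, p) {
  stopifnot(inherits(p, "wca_params"))
  if (any(r <= 0)) stop("WCA potential requires r > 0")
  sr6 <- (p$b / r)^6
  u <- 4 * p$epsilon * (sr6^2 - sr6) + p$epsilon
  ifelse(r < p$r_c, u, 0)
}

#' @rdname wca_energy
#' @export
wca_force <- function(r, p) {
  stopifnot(inherits(p, "wca_params"))
  if (any(r <= 0)) stop("WCA potential requires r > 0")
  sr6 <- (p$b / r)^6
  f <- 4 * p$epsilon * (12 * sr6^2 - 6 * sr6) / r
  ifelse(r < p$r_c, f, 0)
}

#' FENE bond parameters
#'
#' Finitely extensible nonlinear elastic bond in the LAMMPS convention:
#' an attractive logarithmic spring diverging at the maximum extension
#' `R0`, combined with the short-range WCA/Lennard-Jones repulsion of the
#' bonded pair.  The lipid model uses `K = 30` epsilon/sigma^2 and
#' `R0 = 1.5` sigma.
#'
#' @param K Spring constant (epsilon/sigma^2). Default 30.
#' @param R0 Maximum bond extension (sigma). Default 1.5.
#' @param wca [wca_params()] for the repulsive term folded into the bond.
#' @return An object of class `fene_params`.
#' @export
fene_params <- function(K = 30, R0 = 1.5, wca = wca_params()) {
  stopifnot(K > 0, R0 > 0, inherits(wca, "wca_params"))
  structure(list(K = K, R0 = R0, wca = wca), class = "fene_params")
}

#' FENE bond energy and force
#'
#' Energy is `-0.5 K R0^2 log(1 - (r/R0)^2)` plus the WCA repulsion.
#' The bond is undefined at or beyond `R0`: evaluation there signals an
#' overstretched-bond error (a simulation hitting it must abort).
#'
#' @param r Bond length(s), sigma units; `0 < r < R0`.
#' @param p A [fene_params()] object.
#' @param include_wca If `FALSE`, return only the attractive logarithmic
#'   term (useful for testing against tabulated values).
#' @return Energy (epsilon) or force `-dU/dr` (epsilon/sigma; positive
#'   pushes the beads apart).
#' @export
fene_energy <- function(r, p, include_wca = TRUE) {
  stopifnot(inherits(p, "fene_params"))
  if (any(r <= 0)) stop("FENE bond requires r > 0")
  if (any(r >= p$R0)) {
    stop(sprintf("overstretched FENE bond: r = %.4f >= R0 = %.4f",
                 max(r), p$R0))
  }
  u <- -0.5 * p$K * p$R0^2 * log(1 - (r / p$R0)^2)
  if (include_wca) u <- u + wca_energy(r, p$wca)
  u
}

#' @rdname fene_energy
#' @export
fene_force <- function(r, p, include_wca = TRUE) {
  stopifnot(inherits(p, "fene_params"))
  if (any(r <= 0)) stop("FENE bond requires r > 0")
  if (any(r >= p$R0)) {
    stop(sprintf("overstretched FENE bond: r = %.4f >= R0 = %.4f",
                 max(r), p$R0))
  }
  f <- -p$K * r / (1 - (r / p$R0)^2)
  if (include_wca) f <- f + wca_force(r, p$wca)
  f
}

#' Harmonic angle parameters
#'
#' Keeps the three beads of a lipid straight: `U = K (theta - theta0)^2`
#' with `theta0 = pi` (180 degrees) and `K = 10` epsilon/rad^2.  Note the
#' convention without a 1/2 factor, matching the engine-standard harmonic
#' angle style.
#'
#' @param K Stiffness (epsilon/rad^2). Default 10.
#' @param theta0 Equilibrium angle (radians). Default `pi`.
#' @return An object of class `angle_params`.
#' @export
angle_params <- function(K = 10, theta0 = pi) {
  stopifnot(K > 0, theta0 >= 0, theta0 <= pi)
  structure(list(K = K, theta0 = theta0), class = "angle_params")
}

#' Harmonic angle energy
#'
#' @param theta Angle(s) in radians, in `[0, pi]`.
#' @param p An [angle_params()] object.
#' @return Energy in epsilon; exactly 0 at `theta0`, symmetric about it.
#' @export
angle_energy <- function(theta, p) {
  stopifnot(inherits(p, "angle_params"))
  if (any(theta < 0 | theta > pi)) stop("angle must lie in [0, pi]")
  p$K * (theta - p$theta0)^2
}

#' Cosine-squared attraction parameters
#'
#' The broad attractive well that replaces explicit solvent in the
#' three-bead lipid model: a flat minimum of depth `epsilon` out to the
#' onset `r_c`, decaying smoothly to zero as `cos^2` over a width `w_c`.
#' For tail-tail pairs `r_c = 2^(1/6)` sigma (the WCA cutoff) and
#' `w_c = 1.5` sigma; `w_c` tunes membrane fluidity at fixed temperature.
#'
#' @param epsilon Well depth (epsilon units).
#' @param r_c Onset of the decay (sigma units).
#' @param w_c Decay width (sigma units), strictly positive.
#' @return An object of class `cosine_params`.
#' @export
cosine_params <- function(epsilon = 1, r_c = 2^(1 / 6), w_c = 1.5) {
  if (w_c <= 0) stop("cosine attraction requires w_c > 0")
  stopifnot(epsilon >= 0, r_c > 0)
  structure(list(epsilon = epsilon, r_c = r_c, w_c = w_c),
            class = "cosine_params")
}

#' Cosine-squared attraction energy and force
#'
#' `U(r) = -epsilon` for `r <= r_c`;
#' `U(r) = -epsilon cos^2(pi (r - r_c) / (2 w_c))` for
#' `r_c < r <= r_c + w_c`; 0 beyond.  Continuous everywhere.
#'
#' @param r Separation(s), sigma units, strictly positive.
#' @param p A [cosine_params()] object.
#' @return Energy (epsilon) or central force `-dU/dr` (epsilon/sigma).
#' @export
cosine_attraction_energy <- function(r, p) {
  stopifnot(inherits(p, "cosine_params"))
  if (any(r <= 0)) stop("cosine attraction requires r > 0")
  x <- pi * (r - p$r_c) / (2 * p$w_c)
  u <- ifelse(r <= p$r_c, -p$epsilon,
              ifelse(r <= p$r_c + p$w_c, -p$epsilon * cos(x)^2, 0))
  u
}

#' @rdname cosine_attraction_energy
#' @export
cosine_attraction_force <- function(r, p) {
  stopifnot(inherits(p, "cosine_params"))
  if (any(r <= 0)) stop("cosine attraction requires r > 0")
  x <- pi * (r - p$r_c) / (2 * p$w_c)
  # dU/dr = epsilon * (pi / 2 w_c) * sin(2x); force = -dU/dr (attractive)
  f <- ifelse(r <= p$r_c | r > p$r_c + p$w_c, 0,
              -p$epsilon * pi / (2 * p$w_c) * sin(2 * x))
  f
}

#' Ligand-receptor coupling parameters
#'
#' The ligand-receptor attraction is the cosine-squared well scaled to be
#' much shorter-ranged than the tail-tail attraction: onset
#' `r_c = 2^(1/6)` sigma and width `w_c = 0.45` sigma (0.3 times the
#' tail-tail width of 1.5 sigma), with a well depth `epsilon_LR` of
#' 20 epsilon unless stated otherwise.  With this geometry the magnitude
#' of the potential at the 1.5-sigma rupture separation is 1.25 epsilon.
#'
#' The same function is used by both coupling schemes:
#' \describe{
#'   \item{`mode = "pair"`}{an unrestricted distance-dependent pair
#'     potential acting between every ligand/receptor-head pair, so one
#'     ligand can attract several receptors at once (uncontrolled
#'     valency);}
#'   \item{`mode = "bond"`}{a valence-limited dynamic bond: an unbound
#'     ligand-receptor pair closer than `r_form` forms an explicit bond
#'     with probability `p_form` per step (subject to `valence_cap` on
#'     both partners), the bond carries the identical potential, and it
#'     ruptures when stretched beyond `r_break`.}
#' }
#'
#' @param epsilon_LR Well depth (epsilon units). Default 20.
#' @param r_c Onset of the decay (sigma). Default `2^(1/6)`.
#' @param w_c Decay width (sigma). Default 0.45.
#' @param r_form Bond-formation search radius (sigma). Default 2.
#' @param p_form Per-step bond-formation probability. Default 0.5.
#' @param r_break Rupture length (sigma). Default 1.5. Must be < `r_form`.
#' @param valence_cap Maximum simultaneous bonds per ligand and per
#'   receptor. Default 1. `Inf` disables the cap.
#' @param mode `"bond"` (valence-limited, the recommended scheme) or
#'   `"pair"` (unrestricted pair potential).
#' @return An object of class `lr_params` (also a valid `cosine_params`
#'   for the energy functions).
#' @export
#' @examples
#' p <- lr_params()
#' abs(ligand_receptor_energy(1.5, p))  # ~1.25 epsilon at rupture
lr_params <- function(epsilon_LR = 20, r_c = 2^(1 / 6), w_c = 0.45,
                      r_form = 2, p_form = 0.5, r_break = 1.5,
                      valence_cap = 1, mode = c("bond", "pair")) {
  mode <- match.arg(mode)
  if (r_break >= r_form) stop("r_break must be smaller than r_form")
  stopifnot(epsilon_LR >= 0, w_c > 0, p_form >= 0, p_form <= 1,
            valence_cap >= 1)
  structure(list(epsilon = epsilon_LR, r_c = r_c, w_c = w_c,
                 r_form = r_form, p_form = p_form, r_break = r_break,
                 valence_cap = valence_cap, mode = mode),
            class = c("lr_params", "cosine_params"))
}

#' Ligand-receptor potential energy and force
#'
#' Identical in both coupling modes: the scaled cosine-squared well of
#' [lr_params()].
#'
#' @param r Separation(s), sigma units.
#' @param p An [lr_params()] object.
#' @return Energy (epsilon) or central force (epsilon/sigma).
#' @export
ligand_receptor_energy <- function(r, p) {
  stopifnot(inherits(p, "lr_params"))
  cosine_attraction_energy(r, p)
}

#' @rdname ligand_receptor_energy
#' @export
ligand_receptor_force <- function(r, p) {
  stopifnot(inherits(p, "lr_params"))
  cosine_attraction_force(r, p)
}

#' Interaction support of the ligand-receptor potential
#'
#' `r_c + w_c`, beyond which the pair potential is exactly zero.  Used as
#' the "bound" criterion in pair-mode valency measurements.
#'
#' @param p An [lr_params()] object.
#' @return Length in sigma units (about 1.572 for the defaults).
#' @export
lr_binding_cutoff <- function(p) {
  stopifnot(inherits(p, "lr_params"))
  p$r_c + p$w_c
}

#' Tabulate the ligand-receptor potential for use as a bond style
#'
#' Produces the table used when the coupling runs as a dynamic bond:
#' an evenly spaced grid on `(0, r_form]` with the energy from
#' [ligand_receptor_energy()] and the analytic force `-dU/dr` (not a
#' finite difference).  Beyond the interaction support the potential is
#' zero: a freshly formed bond longer than the support carries no force
#' until it shortens or ruptures.
#'
#' @param p An [lr_params()] object.
#' @param n_points Number of grid points (>= 2). Default 2000, which
#'   keeps linear-interpolation error below 1e-3 epsilon.
#' @return A data.frame with columns `r`, `U`, `F`.
#' @seealso [write_potential_table()] to write the engine-standard
#'   tabulated-potential text file.
#' @export
tabulate_bond_potential <- function(p, n_points = 2000) {
  stopifnot(inherits(p, "lr_params"), n_points >= 2)
  r <- seq(p$r_form / n_points, p$r_form, length.out = n_points)
  data.frame(r = r,
             U = ligand_receptor_energy(r, p),
             F = ligand_receptor_force(r, p))
}
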