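---
title: "Methods: coarse-grained membrane wrapping and ligand valency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained membrane wrapping and ligand valency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(memwrap)
```

## The problem

When coarse-grained molecular dynamics is used to study how a lipid
membrane wraps (endocytoses) a ligand-decorated nanoparticle, the
ligand-receptor adhesion is very often modelled as a purely
distance-dependent *pair potential*.  A pair potential has no notion of
saturation: nothing stops three, four or five receptor lipids from
nestling into the attraction well of a single ligand bead.  The number
of receptors simultaneously bound to one ligand — the *valency* X —
then becomes an uncontrolled function of nanoparticle curvature,
interaction strength, and ligand/receptor concentration.  Because the
driving force for wrapping is the *total* adhesion energy, an
uncontrolled valency silently rescales that driving force and corrupts
comparisons between nanoparticle sizes, coverages and binding
strengths.

`memwrap` implements both coupling schemes behind one switch so the
artifact can be measured rather than guessed at:

* **pair mode** — the conventional unrestricted pair potential;
* **bond mode** — a valence-limited scheme in which the *same*
  potential acts only through explicit, dynamically created and
  ruptured ligand-receptor bonds, with at most `valence_cap` bonds per
  ligand and per receptor (default 1).

Since the potential energy function of a bound pair is identical in the
two schemes, any difference in behaviour is attributable to valency
alone.

## The model

**Lipids.** The implicit-solvent three-bead lipid (one head, two tail
beads).  Within a lipid, beads are connected by FENE bonds
(`K = 30 eps/sigma^2`, maximum extension `R0 = 1.5 sigma`, with the
usual short-range WCA/LJ repulsion folded in) and kept straight by a
harmonic angle `U = K2 (theta - pi)^2` with `K2 = 10 eps/rad^2` (the
engine-standard convention without the 1/2 factor).  All bead pairs
repel through the WCA potential, `b = 0.95 sigma` for pairs involving
head (or receptor-head, or nanoparticle) beads and `b = 1 sigma` for
tail-tail pairs; tail beads additionally attract through the broad
cosine-squared well of depth `1 eps` with onset `2^(1/6) sigma` and
width `w_c`.  At `kT = 1 eps` and `w_c = 1.5 sigma` the bilayer is
fluid and self-sustaining.

**Receptors** are ordinary lipids whose head bead carries one extra
attraction (below); they are a seeded uniform sample of the
nanoparticle-facing leaflet.  The stated receptor percentage is
interpreted *per facing leaflet*: at 20% a 10,452-lipid membrane
carries `floor(0.2 x 5226) = 1045` receptors, which matches the
reported count, whereas 20% of all lipids (2090) does not.  A
`receptor_basis = "membrane"` switch provides the other reading.

**Nanoparticle.** A rigid sphere of radius R whose surface carries
`floor(4 pi R^2)` beads on a Fibonacci (golden-angle) lattice — a
deterministic construction with near-uniform ~1 sigma neighbour
spacing.  This bead count reproduces the reported 904 ligands for a
12-sigma sphere at 50% coverage via `floor(0.5 x floor(4 pi 144))`.
Ligands are a seeded uniform sample of the surface beads.  The sphere
moves as one rigid body (quaternion dynamics driven by the summed
per-bead forces and torques, including the per-bead thermostat forces).

**Ligand-receptor coupling.** The same cosine-squared well, scaled
short: width `w_c_LR = 0.45 sigma` (0.3 times the tail-tail width) and
depth `epsilon_LR` (default `20 eps`).  The onset is fixed at
`2^(1/6) sigma`; with that geometry the magnitude of the potential at
the 1.5-sigma rupture separation is 1.25 eps, the value the scheme is
calibrated against, and the interaction support ends at
`~1.572 sigma`.  In pair mode the well acts between every
ligand/receptor-head pair.  In bond mode it is evaluated only across
live bonds (the tabulated-bond writer `write_potential_table()`
produces the identical curve for use in external engines); bonds longer
than the support are slack (zero force) until they shorten or rupture.

**Bond dynamics.** Once per timestep, in this order: (1) every live
bond longer than `r_break = 1.5 sigma` ruptures; (2) every unbound
ligand-receptor pair within `r_form = 2 sigma` is visited in a seeded
random order and forms a bond with probability `p_form = 0.5`, provided
both partners are below the valence cap.  Rupture-before-formation
means a bond created in the `(1.5, 2]` sigma window survives until at
least the next step's rupture check; the random traversal removes any
spatial bias in which receptor wins a contested ligand.  With
`valence_cap = Inf`, `p_form = 1` and `r_form` set to the interaction
support, one update reproduces pair mode's binding graph exactly — the
equivalence limit the test suite asserts.

## Integration and ensemble

Velocity-Verlet with the Langevin thermostat applied as a
friction-plus-noise force (`damp = 1 tau`, `kT = 1 eps`,
`dt = 0.01 tau`), the convention of the common MD engines.  The
thermostat noise comes from a dedicated xoshiro256** stream seeded per
run, so a (state, seed) pair reproduces a trajectory bitwise,
independent of R's RNG.

**Zero tension.** The membrane must be tensionless so that bending, not
stretching, governs wrapping.  The reference implementation names a
Nosé–Hoover barostat in the XY plane; `memwrap` uses a Berendsen-style
proportional rescale toward zero lateral tension instead — the contract
is the zero *mean* lateral tension, not the barostat's microscopic
ensemble, and the proportional scheme is simpler and unconditionally
stable.  Two details matter:

* the relaxation couples to the **areal tension** `P_lat * Lz` rather
  than the volume-diluted pressure, so the rate does not depend on how
  much empty height the box carries (`Lz` defaults to 60 sigma so the
  membrane never sees its periodic image);
* `Lx` and `Ly` are coupled jointly (isotropic in-plane), and `Lz` is
  fixed.

With `pdamp = 10^3 tau` a 512-lipid patch started from a
1.2-sigma^2/lipid lattice relaxes to its equilibrium area within a few
hundred tau.  On that patch the measured equilibrium area per lipid is
~1.17 sigma^2, i.e. an extrapolated lateral edge of ~78 sigma for a
10,452-lipid membrane, within 2% of the reported 77 x 77 sigma box.

**Neighbour search.** A cell list builds a Verlet pair list with
per-species-pair cutoffs (tail-tail pairs need `2^(1/6) + w_c`,
head-involved pairs only their WCA cutoff, ligand-receptor pairs the
formation radius in bond mode) plus a 0.4-sigma skin; the list is
rebuilt when any bead has moved half the skin.  Positions are rewrapped
at every rebuild so minimum-imaging reduces to a single fold.  Boxes too
small for a 3x3x3 cell decomposition fall back to a complete O(N^2)
build of the same list.

**Numerical care.** Lipid angles sit near 180 degrees, where
`acos`/`sqrt(1 - c^2)` lose precision catastrophically; the angle force
uses the cross-product form `atan2(|d1 x d2|, d1 . d2)`, which is
well-conditioned there (this measurably removes secular NVE drift).
An overstretched FENE bond (r >= R0) or a non-finite coordinate aborts
the run with a diagnostic rather than propagating garbage.

## Measurements

* **Binding graph / valency.** In bond mode the live bond set; in pair
  mode every ligand/receptor pair within the interaction support
  (~1.572 sigma) — stated explicitly because no numeric "bound"
  cutoff is given by the source convention.  Frame valency is total
  edges / ligand count; the time-averaged valency X averages frame
  means over frames at or after `wrap_time + 100 tau`, so the value
  describes the equilibrated, fully wrapped state.
* **Wrapping time.** The reference work never defines "completely
  wrapped" operationally.  `memwrap` uses: the first sampled time at
  which the bound-ligand fraction reaches 0.95 and stays there for
  10 tau.  Both numbers are arguments of `wrapping_time()`, and raising
  the threshold can only delay the detected time (a property test).
* **Percent error.** `100 (T_u^NV - T_u^IV) / T_u^IV` between the
  valence-unlimited (NV) and imposed-valence (IV) schemes, computed
  per replicate and then summarized (mean and spread); unwrapped
  replicates are flagged, never silently averaged.  The sign convention
  (positive = unlimited scheme slower) is a package choice, documented
  here because the source formula is not printed in the text.
* **Energy diagnostic.** With both systems fully wrapped and otherwise
  identical, `(U_bond - U_pair) / (eps_LR N_L) + 1` estimates the
  pair-mode valency from potential energies alone — a quick test for
  uncontrolled valency, accurate to roughly half a receptor because
  bound pairs do not all sit at full well depth.
* **Membrane observables.** Kinetic temperature against equipartition;
  area per lipid `Lx Ly / (n/2)` and the lateral edge extrapolated to
  any lipid count.  The calibration `sigma = 0.9 nm`, `tau = 1 ns` is
  available through `to_physical_units()`.

## Scaling rules for experiments

Curvature sweeps hold the maximum total binding energy
`E_max = N_L x eps_LR` constant across radii
(`epsilon_for_constant_total_binding()`); the fig2 preset anchors
`E_max` to a 20-eps-per-ligand sphere of radius 7 sigma (the anchor is
a package choice — any anchor gives the same relative comparison).
`rescale_epsilon_by_valency()` implements the reported mitigation
`eps_LR = eps_o / X`; on the two printed rows the quotient reproduces
the reported depths only to ~0.015 eps (20/5.15 = 3.883 vs 3.87),
which we document rather than absorb — the printed table was likely
rounded from unrounded valencies.

## Problem sizes

The full-scale experiments (10,452- or 16,296-lipid membranes, radii
7-17 sigma, 10^4 tau, five replicates per condition) are what the
`preset_experiment()` grids describe at `scale = 1`; they are
cluster-scale jobs.  The package's own test surface uses desk-scale
problem sizes chosen to exercise every code path with meaningful
physics:

* tensionless equilibration and the area-per-lipid extrapolation on a
  512-lipid patch over 800 tau;
* the valency artifact on a 1,000-lipid patch with an R = 5 sigma
  sphere (157 ligands, 250 receptors): 1,500 tau in pair mode — enough
  for the sphere to diffuse into contact (~400 tau at this geometry)
  and for adsorption to mature — against 600 tau in bond mode, whose
  X <= 1 claim is a per-frame invariant of the cap rather than a
  long-time average.  Pair mode's mean valency over all ligands climbs
  through 2 near 1,000 tau and keeps rising while wrapping proceeds;
  the effect is asserted by direction (X > 2 vs X <= 1), not magnitude.
  When the 95% bound-ligand wrapping threshold has not yet been
  reached, the average is taken over the final 100 tau and reported as
  provisional;
* conservation, equipartition and determinism checks on 50-lipid
  patches.

## What the synthetic systems do and do not show

The builders generate idealized flat bilayer patches and perfectly
rigid, uniformly decorated spheres.  They emulate the geometry,
composition and coupling of the full-scale study, so tests on them
validate the force field, integrator, bond dynamics and analysis
pipeline.  They do not capture membrane-reservoir effects (a small
patch under wrapping loses projected area faster than a large one),
receptor depletion at realistic (much lower) receptor densities,
nanoparticle flexibility or nonspherical shapes, or any chemistry of
specific ligand-receptor pairs.  Quantitative valencies and wrapping
times at desk scale therefore differ from the full-scale values; the
invariants (valence cap, scheme equivalence limits, tensionless
contract, conservation laws) transfer unchanged.

## Known limitations

* The Berendsen-style barostat yields the correct mean area but not the
  exact fluctuation spectrum of a true Nosé–Hoover XY barostat.
* Checkpoints store positions, velocities, topology and the live bond
  set, but not the thermostat RNG mid-stream state; a continuation run
  is seeded afresh (record the new seed for provenance).
* One rigid body per system (a single nanoparticle).
* In bond mode, ligands and receptors interact only through WCA plus
  their live bonds; there is no residual LR attraction for unbonded
  pairs (the pair scheme applies it to all pairs).  This is the
  intended contrast, but it means bond mode's adsorption kinetics rely
  on diffusion into the 2-sigma formation shell.
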