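---
title: "Methods: membrane-peptide pore-formation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane-peptide pore-formation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mempore)
```

`mempore` analyses molecular trajectories of membrane-bound peptide
aggregation and channel formation.  This vignette documents the models
behind each estimator, the tunable parameters and their defaults, the
design choices made where the methodology was genuinely open, and what
the synthetic generators do and do not emulate.

## Units, containers and geometry

Internal units are nm, ns, amu, kcal/mol and K throughout; the gas
constant is `R_KCAL` = 1.987204e-3 kcal/(mol K), so every printed energy
is in kcal/mol.  A trajectory is a topology (particles labelled by role —
peptide, lipid head/tail, water, ion — and, for peptides, by chain) plus
an ordered list of frames with strictly increasing times and orthorhombic
boxes.  Triclinic boxes are rejected.  Particle indices are 1-based, the
natural R convention; file formats are 1-based anyway.

Periodic geometry uses the minimum-image convention with components mapped
into `[-L/2, L/2)`.  Chains are assumed stored whole; where an operation
needs a whole molecule (COM, Rg, chain axes) a minimum-image chaining pass
along the bonded sequence rebuilds wrapped chains first, which is exact
whenever consecutive bonded particles are less than half a box apart.

Frames are read and written in a plain-text multi-frame GRO dialect
(concatenated GRO blocks, frame times in the title lines), with roles
inferred from residue/atom names through a declarative map in the
configuration, so coarse-grained and atomistic naming dialects are both
supported without code changes.  PDB topologies are read through `bio3d`
when installed.  Coarse-grained defaults are a bead mass of 72 amu (the
common 4-to-1 mapping) and a van der Waals radius of 0.235 nm (half the
common 0.47 nm bead diameter); both are configuration-exposed, and the
equal-mass default makes mass-weighted and geometric COMs coincide for
bead chains.

## Clustering and aggregation kinetics

Two chains belong to the same cluster iff the minimum-image distance
between their centres of mass is *strictly* below the cutoff (default
1.5 nm); the partition is the transitive closure (single linkage,
connected components, computed with `igraph`).  Strict inequality and the
single-linkage reading are deliberate conventions: cluster *counting*
implies connected components rather than cliques, and the boundary case
is fixed once rather than left to floating-point accident.  PBC-aware
distances are used because membrane-bound peptides diffuse across the
periodic cell.  The COM weighting (mass vs geometric) is configurable;
mass-weighted is the default.

## Conformation metrics

**Radius of gyration** is the mass-weighted RMS distance from the COM,
over unwrapped selections.

**SASA** uses the Shrake–Rupley construction: each particle carries a
deterministic Fibonacci-lattice point set (default 960 points) scaled to
its expanded radius (vdW + probe); points inside any neighbour's expanded
sphere are buried, and the accessible fraction times the expanded-sphere
area sums to the SASA.  The deterministic lattice makes areas reproducible
without a seed; at 960 points the isolated-sphere closed form
`4π(r+p)²` is reproduced to well under 1%.  The probe radius default of
0.14 nm is the water convention, retained even for coarse-grained beads —
a documented convention, not physics.  Exactly coincident equal spheres
are a degenerate tie; the implementation assigns the shared surface to the
lower-indexed particle so the area is counted once.  The selection is all
peptide particles by default; a `sasa_context = "with_lipids"` switch
makes lipid particles occlude the peptide surface without contributing
area, for systems where burial by the bilayer should be modelled.

**Order parameter.** Each chain's axis is the dominant principal axis of
its backbone particles, sign-aligned to +z; `S` is the largest eigenvalue
of the nematic tensor `Q = mean((3 u u' - I)/2)` over chain axes.  This
is the standard nematic order parameter: 1 for a perfectly parallel
bundle, about 0 for isotropic axes, range `[-0.5, 1]`, and invariant to
flipping any axis since `Q` is quadratic in `u`.  The nematic reading was
chosen because "more parallel arrangement" is exactly what nematic order
quantifies; a mean-P₂-to-z alternative would differ only for bundles
tilted collectively away from the membrane normal.

## Free-energy landscape over (SASA, Rg)

The per-frame (SASA, Rg) series is histogrammed on a regular grid
(default 50 × 50 bins; range = observed min/max padded by half a bin) and
normalised; Boltzmann inversion gives `W = -RT ln P` on occupied bins,
shifted so the global minimum is zero, so basin depths and barrier
heights read directly off `W`.  Three numerical conventions matter:

* **Empty bins stay undefined** (`NA`, conceptually +inf) — `-RT ln 0`
  must never silently become a finite number, and saddle paths cannot
  cross unobserved regions.
* **No smoothing by default**: the histogram is inverted as observed.
* **Basins** are occupied bins no higher than all 8-connected occupied
  neighbours; connected plateaus of tied minima collapse to one
  representative (so a perfectly flat landscape yields a single basin),
  and shallower candidates within a minimum bin separation (default 3) of
  a deeper one are dropped.  **Barriers** use the minimax (saddle) path:
  among 8-connected paths of occupied bins, the one whose maximum `W` is
  least; the forward barrier is saddle − W(a), backward saddle − W(b), so
  forward − backward = W(b) − W(a) exactly and the saddle is symmetric in
  its endpoints.  4-connectivity is available by configuration.

The choice of 50 × 50 bins and single-series input are the package's
defaults, configuration-exposed; multiple replicate series can be pooled
by concatenation before histogramming.

## Axial density, PMF, contacts, permeation, pore radius

**Density.** `ρ(z)` is the time-averaged count of a species inside a
channel-centred sampling cylinder (default radius 1.0 nm, axis at the box
centre unless given), per z bin over the channel span (default
2.32–6.55 nm), divided by the bin volume `π r² Δz`.  Channel PMFs are
conventionally cylinder-sampled; because no universal convention exists
for the cross-section, the radius is surfaced rather than hidden.  The
bulk density comes from the slabs at least 1 nm beyond the channel span.
Two bulk cross-sections are supported: the full box cross-section (the
default, appropriate for a solvated box) and the sampling cylinder itself
(`bulk_cross_section = "cylinder"`, appropriate when — as in the
Boltzmann-ensemble generator — particles are confined to the cylinder by
construction, since a box-wide bulk over a disc-confined ensemble would
shift every PMF bin by `RT ln(box area / disc area)`).

**PMF.** `ΔG_PMF(z) = -RT ln(ρ_z/ρ_bulk)` on bins with nonzero density;
empty bins are undefined, never zero.  The barrier is the maximum defined
value over the span.  This density-based PMF is a rough relative
free-energy profile, not an equilibrium PMF; umbrella-sampling analysis
is explicitly out of scope.

**Contacts.** A solvent particle is in direct contact iff its
minimum-image distance to any peptide particle of the cluster is strictly
below 0.4 nm; the complement inside the cylinder is reported as the
"water network" population.

**Permeation.** An event is a particle entering the slab `[z_lo, z_hi]`
through one face and exiting through the opposite face while remaining in
the cylinder for every frame spent inside; retreats back out of the entry
face reset the traversal and are never counted.  Face crossings are
resolved with minimum-image z steps, so counts are invariant to
frame-wise rewrapping, and a particle that wraps across the periodic
boundary (top to bottom without passing the slab) only changes side.
Entry/exit times are the frame times bracketing the traversal.  No
minimum residence time is imposed; frame spacing is assumed fine enough
that a particle does not cross more than one face per step.

**Pore radius.** Cluster peptide particles are projected as discs of
their vdW radii onto the x–y plane (optionally restricted to the channel
z-span), rasterised (default 0.02 nm cells), and the free space is
flood-filled from the cluster's COM projection.  If the filled component
is enclosed (never reaches the raster edge) its area `A` gives
`r = sqrt(A/π)`; open geometries (fibers) and covered COM projections
report radius 0 with a diagnostic.  This flood-fill reading of "radius
from the pore area" is one concrete, deterministic definition; it
converges as the grid is refined (halving the spacing moves the estimate
by well under 2% on constructed rings).

## Synthetic generators: what they emulate, and what they do not

The generators provide inputs with known ground truth; they make no claim
of physical realism.

* **Aggregation** (`generate_aggregation_trajectory`): 25 chains of 28
  beads start on a grid at 4.0 nm COM spacing in the membrane plane of a
  20 × 20 × 11 nm box, and random-walk in-plane (Gaussian step, default
  s.d. 0.05 nm/frame over 200 frames of 25 ns — spanning 5 µs) with a
  drift (default 0.5 × step) toward the nearest other cluster.  Clusters
  whose chain COMs come within the 1.5 nm cutoff merge *permanently* and
  move rigidly, annealing into a ring (probability `pore_bias`, default
  0.6) or a line — a kinetic Monte-Carlo-style merge rule chosen because
  the target observable is the cluster count, which this makes
  non-increasing by construction, and no interaction model is available
  to calibrate anything finer.  Defaults were chosen once so that the
  terminal count lands in the handful-of-clusters regime of the real
  kinetics.  The generator does *not* emulate conformational flexibility,
  lipid interactions, peptide expulsion from the membrane, or reversible
  aggregation — so passing tests demonstrate correctness of the
  *estimators*, not realism of membrane biophysics, and say nothing about
  cluster break-up, which real trajectories can show.
* **Boltzmann ensembles** (`generate_boltzmann_particles`): z sampled by
  inverse-CDF on a 10⁴-point grid from `ρ(z) ∝ exp(-U(z)/RT)` for a
  constant, Gaussian-barrier or tabulated `U(z)`; x, y uniform in a
  lateral disc.  This is the exact ground truth for the density-PMF
  chain: the recovered profile converges to `U(z) − min U` as n grows.
  At the tested n = 10⁵ with 0.25 nm bins, a 2.5 kcal/mol barrier is
  recovered with a standard error near 0.1 kcal/mol at the barrier top
  (sparse counts there are the fundamental limitation of density-based
  PMFs near high barriers).
* **Static scenes**: the pore scene places chains vertically on a circle
  of radius `lumen + bead radius`, each chain occupying a few symmetric
  azimuthal columns so that adjacent columns overlap (the ring is closed)
  while every chain's principal axis stays exactly vertical; the lumen
  boundary is therefore slightly scalloped and the recovered radius sits
  within a few hundredths of a nm of the nominal value.  The fiber scene
  is a row of exactly parallel columns with collinear COMs.
* **Two-basin surface** (`fel_reference_surface` / `sample_landscape`):
  two Gaussian wells (depth difference 1.0 kcal/mol) on a plateau at
  2.5 kcal/mol, far apart relative to their width, so the minimax barrier
  equals the plateau by construction; samples are drawn by multinomial
  sampling of a fine grid (400 × 200) of `exp(-W/RT)` with in-cell
  jitter.

All randomness flows from a single integer seed per generator call
through a local RNG scope, so identical scenarios are bit-identical and
the caller's RNG stream is untouched.

## Problem sizes and degenerate inputs

The shipped tests run the estimators at the sizes the statistics require
and the containers comfortably handle: 10⁶ landscape samples, 10⁵
Boltzmann particles, 200-frame/700-particle pipelines, 200 random
clustering frames against a brute-force oracle.  Degenerate inputs are
defined, not accidental: a single particle has Rg 0; a flat landscape has
one basin; identical basins have zero barrier; disconnected basins report
an infinite barrier with a diagnostic; an all-empty histogram, an empty
channel, an empty bulk region and an empty selection are errors.

## Known limitations

* The density-based PMF shares its bulk-normalisation offset across all
  bins; with the box cross-section default, confined ensembles need the
  cylinder bulk option (above).
* Permeation detection assumes the frame spacing resolves single-face
  crossings; trajectories sampled more coarsely than the channel length
  per step would undercount.
* SASA treats the selection in open space; periodic images do not
  occlude.  For membrane-spanning selections near the box edge, recentre
  first.
* The pore radius is a projected-area measure; tilted or hourglass pores
  are summarised by a single effective radius, not a profile.
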