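---
title: "Common-constraints elastic networks for interstate sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common-constraints elastic networks for interstate sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comdyn)
```

## The problem

Coarse-grained force fields of the MARTINI family trade away explicit
backbone hydrogen bonding for speed, and compensate with an *elastic
network*: harmonic restraints between backbone beads (one bead per
residue, placed at the C-alpha position) whose reference distance lies
inside a cutoff shell. The network is built from one experimental
structure, so it pins the protein to that conformational state. For a
membrane transporter that must cycle between an inward-open and an
outward-facing state — the rocker-switch mechanism of MFS-fold sugar
transporters such as GLUT1 and GLUT3 — a single-state network makes the
functional transition unobservable by construction.

The remedy implemented here is a *common-constraints* network: build the
single-state network as usual, then keep only those constraints whose
reference distance agrees between the two end-state structures, within a
threshold of 0.1 nm (1 Å). Constraints that encode one state are removed;
what remains restrains only the geometry the states share, so the fold is
maintained while the interstate motion becomes one of the network's soft
degrees of freedom. The filter is applied per state (state A's network
filtered against state B and vice versa), so the two filtered networks
generally differ in size.

## Parameters and their defaults

* **Elastic shell** `lower_cutoff = 0.5`, `upper_cutoff = 0.9` nm and
  **force constant** `k = 500` kJ mol^-1 nm^-2: the standard martinize
  elastic-network convention. These are first-class configuration
  because published constraint counts can only be reproduced with the
  same build parameters the original topology used.
* **Sequence separation** `min_seq_sep = 3` (within a chain): the two
  nearest backbone neighbours are maintained by bonded terms of the
  coarse-grained topology, not by the network. Cross-chain pairs are
  always eligible.
* **Common-constraints threshold** `comdyn_threshold = 0.1` nm,
  compared inclusively (`<=`); a strict `<` is available
  (`strict = TRUE`). Raising the threshold removes more constraints and
  risks unfolding; lowering it re-pins the start state.
* **Unmapped endpoints**: when the two states are different proteins
  (e.g. GLUT1 vs GLUT3), residues are paired by end-gap-free global
  sequence alignment (BLOSUM62, gap open 10, extend 0.5), by identity of
  residue numbering, or by an explicit table. A constraint whose
  endpoint has no counterpart cannot be verified across states and is
  dropped by default (`unmapped = "keep"` retains it).

All coordinates are handled in nm (PDB Angstrom input is divided by 10
on reading), matching GROMACS conventions; the network is written and
read as a GROMACS `.itp` bonded section.

## Order parameters and distribution statistics

Transporter opening/closing is monitored by distances between the
centroids of 10-residue windows at the intracellular ("in") and
extracellular ("out") ends of the transmembrane helices, computed for
every adjacent pair around the central helix ring (and any configured
cross-rim pair). The centroid is the unweighted mean of the backbone
bead positions: beads are single-site, so no mass weighting applies, and
a centroid-to-centroid distance — rather than closest approach — is the
natural reading of an inter-helix order parameter.

Two ensembles of an order parameter are compared by

* **overlap**: the integral of the pointwise minimum of the two
  normalized densities, a fraction in [0, 1] equal to
  `1 - L1/2`; and
* **shift**: the signed difference of the modal peaks, positive when the
  test ensemble peaks at a larger distance (an opening motion).

The default estimator is a plain histogram with 0.05 nm bins on a shared
grid: the overlap metric is defined as an integral of a pointwise
minimum, which is transparent and exactly computable on a shared
histogram, whereas a kernel estimator would make the metric depend on
bandwidth choices. Peaks are taken from the raw modal bin with ties
broken towards the smaller distance, and no smoothing is applied — so a
reported shift is always a multiple of the bin width.

## Essential dynamics

Collective motions are extracted by principal component analysis of the
fitted coordinate fluctuations: every frame is least-squares superposed
(Kabsch, proper rotation enforced) onto a reference over a bead
selection, and the covariance of the fitted coordinates is
eigendecomposed. The covariance uses the 1/N normalization so that the
variance of the training-set projections along eigenvector *k* equals
eigenvalue *k* exactly — an identity the tests assert to 1e-8. The
fitting reference defaults to the first frame and is configurable (e.g.
a crystal structure). PCA leaves eigenvector signs arbitrary; the
`orient` argument fixes them deterministically by making a chosen
structure (conventionally the outward-like state) project non-positive,
so transition plots always run in the same direction.

## The toy simulator

To exercise the sampling claim end-to-end without a molecular dynamics
engine, the package integrates overdamped (Brownian) Langevin dynamics
on the bead-spring network:

    x <- x - (dt / gamma) * grad U + sqrt(2 kT dt / gamma) * xi

with `U` the sum of harmonic constraint energies plus stiff chain
springs between consecutive beads. First-order dynamics is the cheapest
scheme with the correct Boltzmann stationary distribution; nothing
kinetic is claimed. Chain-spring rest lengths default to the observed
consecutive-bead distances of the start structure — for real C-alpha
traces these are ~0.38 nm, and for idealized fixtures they equal the
generator's spacing, so the start structure is always a force-free
point of the bonded terms. The default timestep `dt = 5e-5` keeps
`dt * k / gamma` below 0.1 for the stiffest default spring (stability of
the Euler scheme); a divergence guard aborts with "unstable timestep" if
any coordinate leaves a sanity bound. Trajectories are bit-reproducible
given the seed.

A single harmonic spring equilibrates to `var(d - d0) = kT/k`
(equipartition), which the tests verify within 10% — the appropriate
check for a thermostatted overdamped integrator, where energy
conservation is not expected.

## The synthetic two-state bundle

The generator emits an idealized ring of six 24-residue helices
(0.15 nm rise per residue, ring radius 0.8 nm, helical wind of 100
degrees per residue at 0.23 nm radius) in two states related by a
**rocker** motion: the two half-rings are rigid domains, and state B
rotates one domain by 28 degrees about a horizontal hinge axis through
the bundle centre at mid-height. This geometry was chosen to reproduce,
at toy scale, the *bimodal* character of real interstate distance
changes: intra-domain contacts are exactly invariant (the true common
constraints), seam contacts away from the hinge change by far more than
the 0.1 nm threshold (the state-defining constraints), and only a thin
seam band near the hinge falls in between. Two alternatives were tried
and rejected for cause: a ring-breathing motion makes *every* contact's
change a linear ramp along the membrane normal, which floods the kept
set with constraints just under the threshold whose summed quadratic
cost at the opposite state (~100 kT) freezes the common network; and
straight untwisted rods leave all springs either collinear with a helix
or horizontal, so collective bow/shear modes feel only second-order
restoring forces and even the full single-state network fails to pin
its own state. The breathing motion and the straight-rod option are
retained (`motion = "breathe"`, `twist = FALSE`) because their segment
centroids follow in closed form, which the order-parameter tests use as
an analytic oracle.

With the default bundle, the interstate backbone RMSD is ~0.26 nm, the
state-A network has ~800 constraints of which ~85% are common, and the
dropped 15% are concentrated at the domain seam — so the filtered
network is two rigid bodies joined by a mid-height hinge, with the
rocker rotation as its single soft mode.

## The sampling assay and its calibration

`transition_assay()` runs three simulations from state A: under A's
full network, under B's full network carried onto A's topology, and
under the common-constraints network. Metrics (minimum RMSD to each
state, fraction of frames within an RMSD basin of each state) are
computed after discarding the first 20% of frames as burn-in, so the
run under B's network is scored on its relaxed ensemble rather than on
the shared starting frame. The basin radius is 0.6 of the interstate
RMSD, and the default conditions are `kT = 1` (reduced energy units;
1/500 of the spring constant) for 4e5 steps: at this temperature the
local thermal RMSD floor under a full network (~0.05 nm) sits well
inside the basin radius (~0.16 nm), while the hinge mode freed by the
filter has time to diffuse into the far basin. These values were
calibrated once on the default fixture and are stated here as the study
conditions of the toy assay; they are configuration, not claims about
any real system. Under them, the full-A run never approaches state B
(minimum RMSD ~= the interstate RMSD), the full-B run relaxes into B
and stays, and the common-network run occupies basin A most of the
time with repeated excursions into basin B.

## Numerical choices and degenerate inputs

* Histogram binning anchors bin edges at integer multiples of the bin
  width; a constant series occupies a single bin and integrates to 1.
* `estimate_distribution` rejects zero-width ranges for non-constant
  data; `overlap`/`shift` reject mismatched bin grids rather than
  resampling silently.
* Superposition requires >= 3 beads and a full-rank configuration, and
  always returns a proper rotation (mirror images are never matched).
* Altloc-duplicated C-alphas collapse to the highest-occupancy altloc
  (ties towards "A"); residues with insertion codes receive synthetic
  monotone numbers per chain, with a message.
* `comdyn_filter` on an empty residue map is a hard error; empty
  networks round-trip through the topology format.

## Known limitations

The toy simulator has no excluded volume, no solvent or membrane, and
no inertial dynamics: it demonstrates the *sampling topology* of the
common-constraints idea (which network permits the interstate motion),
not kinetics or thermodynamics of any real transporter. The synthetic
bundle emulates rigid-domain rocking with a single seam; real
transporters superpose local unfolding, loop dynamics and
substrate coupling that the fixture deliberately omits, so passing the
toy assay shows the machinery is correct, not that any particular
protein will transition. Reproducing published constraint counts for
real structure pairs additionally depends on the exact elastic-network
build parameters of the original topology, which published work does
not always record; counts should be compared with an engineering
tolerance, and the alignment-based residue pairing can be replaced by
an explicit conserved-segment table where one is available.
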