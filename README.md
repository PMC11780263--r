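# comdyn

Coarse-grained elastic-network models pin a protein to the single
conformational state they were built from: every bead pair within the
cutoff shell is restrained to its crystallographic distance. For
proteins whose function *is* a conformational transition — the
rocker-switch cycle of MFS-fold sugar transporters such as GLUT1
(inward-open, PDB 5EQI) and GLUT3 (outward-occluded, PDB 4ZW9) being the
motivating case — that construction makes the interesting motion
impossible.

`comdyn` builds the **common-constraints network**: the subset of a
MARTINI-style backbone elastic network whose reference distances agree
between two end-state structures,

> keep constraint (i, j) iff |d_A(i, j) − d_B(m(i), m(j))| ≤ 0.1 nm,

where `m` maps residues of state A onto state B (identity, sequence
alignment, or an explicit table). Constraints encoding one state are
removed; the shared fold geometry remains restrained, and the interstate
motion becomes a soft mode that plain thermal sampling can explore.

The package provides the full surrounding analysis stack:

* **structures** — PDB → one-bead-per-residue (C-alpha) structures in
  nm; residue maps between states or homologs (Biostrings alignment).
* **elastic_network** — martinize-convention network build
  (0.5–0.9 nm shell, k = 500 kJ mol⁻¹ nm⁻², `min_seq_sep` 3), the
  common-constraints filter, GROMACS `.itp` bonded-section I/O.
* **order_params** — inside/outside 10-residue-window centroid
  distances between transmembrane helices around the transporter ring.
* **dist_stats** — overlap (integral of the pointwise minimum of two
  densities) and shift (signed modal-peak difference) between sampled
  distance distributions.
* **essential_dynamics** — Kabsch superposition, covariance/eigenvector
  analysis of pooled ensembles, projection onto the leading collective
  motions.
* **toy_sim** — an overdamped Langevin bead-spring integrator (Rcpp)
  and a three-network transition assay.
* **synthetic_fixtures** — a two-state helix-bundle generator with
  analytically known geometry, so everything above is testable without
  downloads or an MD engine.

A thin command-line tool (`exec/comdyn`) wires the pipeline:
`comdyn fixtures | net build | net filter | sim | assay | op | stats | ed`.

## Worked example

```r
library(comdyn)

# a synthetic two-state rocker bundle with known ground truth
fx <- make_two_state_bundle(bundle_spec(seed = 1))

net_a <- build_network(fx$state_a)
net_a
#> elastic_network 'A': 804 constraints

res <- comdyn_filter(net_a, fx$state_a, fx$state_b, fx$map)
res
#> comdyn_result: kept 682 of 804 constraints (84.8%)
```

85% of state A's constraints are common to both states; the dropped 15%
sit at the seam between the two rigid domains and are exactly the ones
that pin the rocker. Three Langevin runs from state A show what that
means for sampling:

```r
rep <- transition_assay(fx$state_a, fx$state_b, fx$map,
                        cfg = sim_config(n_steps = 4e5, kT = 1,
                                         seed = 1, report_every = 500))
rep
#>   network n_constraints min_rmsd_to_a min_rmsd_to_b frac_basin_a frac_basin_b
#> 1  full_A           804        0.0453        0.2501        1.000       0.0000
#> 2  full_B           896        0.2382        0.0446        0.000       1.0000
#> 3  comdyn           682        0.0652        0.0929        0.855       0.0718
```

Each full single-state network confines the run to its own state (the
minimum RMSD to the other state stays at the interstate distance,
0.26 nm); only the common-constraints network visits both basins —
85% of frames near A, 7% near B, approaching each state to within
0.07–0.09 nm.

Order-parameter distributions are compared the same way mutant and
wild-type ensembles are:

```r
wt  <- make_mutant_like_series(c(2.0, 2.84), weights = c(.5, .5),
                               sigma = 0.05, n = 4000, seed = 1)
mut <- make_mutant_like_series(2.0, sigma = 0.05, n = 4000, seed = 2)
cmp <- compare_ensembles(mut, wt)
sprintf("overlap %.0f%%  shift %+.2f nm", 100 * cmp$overlap, cmp$shift)
#> [1] "overlap 48%  shift -0.80 nm"
```

A variant that samples only one of two wild-type basins overlaps the
pooled wild-type distribution by its basin mass (~50%), and its peak
sits one basin spacing away — the closing direction here, hence the
negative sign.

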