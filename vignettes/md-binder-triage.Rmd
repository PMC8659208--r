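---
title: "Methods: MD-derived descriptors and the binder-triage rubric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MD-derived descriptors and the binder-triage rubric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdtriage)
```

## The problem

BRD9, the bromodomain subunit of the human SWI/SNF complex, remodels its
binding pocket when a ligand enters: the Phe44, Phe47 and Tyr106 side
chains rearrange, and chemically similar scaffolds can differ by orders
of magnitude in affinity.  Semi-rigid docking scores a single static pose
and therefore correlates poorly with measured dissociation constants.
`mdtriage` implements the alternative: run (externally) short replicated
MD simulations of each candidate complex, extract a panel of structural
and energetic descriptors, and combine them into a coarse but honest
four-level triage — Excellent / Good / Intermediate / Bad — that
separates compounds worth synthesising from those that are not.

The package deliberately does not run docking, MD or MM-GBSA itself.  It
consumes their outputs (PDB/DCD trajectories, delimited energy tables)
and owns everything downstream: descriptors, fingerprints, aggregation,
and the decision rule.

## Descriptors and their conventions

**Superposition.**  Every RMSD-type quantity is computed after an optimal
rigid-body (Kabsch/SVD) superposition on a *fit* selection.  Trajectory
files place frames arbitrarily in the simulation box, so skipping the fit
would measure box placement, not conformational change.  The rotation is
always proper (determinant +1); fewer than three points or collinear
references are rejected as degenerate.

**RMSD series** fit on the protein backbone (N, CA, C, O) against frame
1, so the reference value is identically zero and the per-frame series
measures drift from the starting conformation.  The series mean is the
rubric's stability statistic.

**RMSF** uses a two-pass alignment: frames are first aligned to frame 1,
the mean structure is formed, and frames are re-aligned to that mean
before measuring each atom's root-mean-square displacement about its
time-average position.  A one-pass alignment to frame 1 would mix the
reference frame's own noise into every fluctuation.  Residue values are
the mean over backbone atoms and over heavy side-chain atoms separately;
the reported `mean_rmsf` is the mean of those two (or the defined one for
glycine).  The rubric counts binding-site residues with `mean_rmsf`
above 4 Å and tolerates at most 2.

**Radius of gyration** is the root-mean-square distance of the selected
atoms from their *unweighted* centroid.  Mass weighting is deliberately
not used: the quantity tracked is geometric compactness of the heavy-atom
cloud, crystal-derived inputs lack hydrogens, and the unweighted form is
what the distribution-width statistic was defined on.  The width used by
the rubric is the range (max − min) of the per-frame series, compared
against the apo-form width of 0.72 Å.

**Frame clustering** reduces each trajectory to k representative frames
(k = 10 by default; k = 50 when extracting receptors for ensemble
docking).  The clustering variable is one-dimensional — the RMSD from
frame 1 — so k-means is exact enough, but stock k-means is seeded
randomly.  We initialise deterministically at the k quantile midpoints of
the series and run Lloyd iterations, making the procedure a pure function
of its inputs.  The representative of a cluster is the frame nearest the
cluster mean, ties to the lowest frame index.  If the series has fewer
distinct values than k, the achievable number of clusters is returned
with a warning flag rather than fabricating empty clusters.

**Binding-site RMSD and the apo filter.**  `site_rmsd()` fits on the
site *backbone* and scores over all site *heavy* atoms: the question the
filter asks is whether pocket side chains have pre-arranged into a
holo-like geometry, so the fit must not absorb the side-chain signal.
`apo_resemblance()` counts, per holo crystal, the apo snapshots within a
2.5 Å site RMSD, and reports percentages under two denominators — the
filtered snapshot pool and all frames tested — because published tables
have used both conventions (and have printed the all-frames *fraction*
with a percent sign; both numbers are therefore exposed and neither is
reinterpreted).

## Interaction fingerprints

Contact criteria are explicit and configurable
(`contact_criteria()`): hydrogen bonds at ≤ 3.5 Å between N/O heavy
atoms, with a ≥ 120° donor–H–acceptor angle enforced only when the
topology carries hydrogens; hydrophobic contacts at ≤ 3.6 Å between
ligand carbons and carbons of {Ala, Val, Leu, Ile, Pro, Phe, Met, Trp,
Tyr, Cys}; aromatic ring-centroid pairs at ≤ 4.5 Å (ligand rings are
detected as 5/6-membered C/N cycles on a 1.75 Å bond graph); π-cation at
≤ 4.5 Å; ionic pairs at ≤ 3.7 Å with formal charges inferred from
residue/atom names (ligand charges must be declared, as input files carry
none).  MD engines ship their own undocumented geometric definitions; the
contract here is self-consistency — planted contacts are recovered
exactly — not bit-compatibility with any engine.

Each satisfied criterion emits one event per *channel* per frame: H-bond
channels are (ligand atom, protein atom) pairs, hydrophobic channels are
residue-level.  The fingerprint is the fraction of frames each channel is
occupied; the per-residue cumulative fraction sums channels and types and
may exceed 1.  The rubric's interaction count uses the *cumulative*
fraction (threshold 0.5) because that is the quantity the per-residue
fingerprint plots display; whether a single-type rule was ever intended
is unknowable from the published material, and the report metadata
records the convention used.

## Energetics

`kd_to_dg()` implements ΔG = R·T·ln(K_D[M])/1000 with R = 1.987
cal K⁻¹ mol⁻¹.  The temperature is a parameter with default **298.15 K**:
the published experimental affinities are reproduced to the printed
decimal at 298.15 K and not at the 310 K simulation temperature, so the
conversion plainly used standard conditions.  `--temperature` overrides.

MM-GBSA values arrive per cluster representative per replica;
`mmgbsa_summary()` averages within replicas, then across replicas.
Per-residue energies are averaged across replicas
(`per_residue_aggregate()`), with residues missing from some replicas
averaged over the available ones and flagged.

`thresholded_energy_sum()` keeps contributions with **|E| ≥ 5 kcal/mol**.
The magnitude rule (rather than "below −5 only") is the only reading
consistent with published panels that show *positive* site sums, and with
fingerprint plots that label both the ≤ −5 and ≥ +5 tails; a one-sided
mode is available (`rule = "negative"`).  Relatedly, the published table
footnotes attach "all residues" to the site column and vice versa; the
package defines site sum = pocket subset, total sum = all residues, the
only assignment under which |total| ≥ |site| holds in every published
row.  Because the pocket is a subset of the protein, total − site equals
the off-site contribution exactly, a property the tests assert.

`affinity_regression()` regresses calculated on experimental affinity;
R² equals the squared Pearson correlation so the axis choice is
immaterial.  On the eight training pairs the package obtains R² ≈ 0.30
(the original report printed 0.31; re-deriving it from the printed values
cannot reach that figure, and the difference is surfaced rather than
matched).

## The rubric

The published ranking rules are qualitative bullets applied with
case-by-case judgment.  `predict_triage()` freezes them into an explicit
tree:

1. If MM-GBSA ≤ −70, site sum ≤ −15 and contacts ≥ 3 → top tier;
   within it, **Excellent** iff total sum ≤ −50 and contacts ≥ 4, else
   **Good**.
2. Otherwise **Intermediate** iff total sum ≤ −30, or (site sum ≤ −15
   and MM-GBSA ≤ −65), or (site and total sums coincide within 0.01
   kcal/mol and MM-GBSA ≤ −65) — the coincident-sums clause encodes
   "the whole binding energy comes from pocket residues", a modest but
   genuine binder.
3. Otherwise **Bad**.

The four energy thresholds (−70/−65, −15, −50/−30 kcal/mol) were fitted
once so the tree reproduces every published label of both the training
and the external test panels, and they are exposed in
`triage_thresholds()` rather than hard-coded; every report prints the set
in force.  The Excellent/Good split is this package's formalisation — the
original narrative distinguishes only top/middle/bottom but labels its
best compound separately, and the split criterion (strong total energy
plus a dense fingerprint) is what isolates exactly those systems.
Docking score and static-pose contacts are displayed but never decide:
the central finding being operationalised is that docking alone
misguides selection.  Likewise RMSD/RMSF/Rg produce traffic lights for
the report but do not move the label; they proved insufficient to
separate good binders from bad.

`predict_triage()` is monotone in each energy argument (making any energy
more negative never demotes a compound), a property the suite checks on
randomly generated panels.  Ranking orders by tier, ties by MM-GBSA.

## The synthetic generator

`make_toy_structure()` builds an idealised chain (N/CA/C/O backbone, 0–4
heavy side-chain atoms, a residue palette spanning glycine, hydrophobic,
polar and charged types) with an optional 6-atom ligand near a designated
pocket.  `simulate_trajectory()` adds iid Gaussian jitter with
per-residue amplitudes, applies an accumulating rigid-body drift, and
realises contact schedules by moving one designated ligand atom (jitter-
free) to 2.9 Å / 3.2 Å of the target residue in exactly the scheduled
share of frames and to 9.5 Å otherwise, so the corresponding channel
fraction is recovered *exactly*.  Everything is a pure function of the
seed.

What this emulates: the statistical structure the descriptors assume —
known fluctuation amplitudes (isotropic σ per axis gives an expected
atomic RMSF of √3·σ), rigid motions that superposition must cancel,
contact occupancies, and energy tables with known means.  What it does
not emulate: time-correlated dynamics, anharmonic transitions, solvent,
force-field physics, or realistic kinetics.  Passing tests therefore
demonstrate estimator correctness (the right formula, correctly
implemented), not that 100-ns explicit-solvent observables are
reproduced; the published per-trajectory RMSD/RMSF/Rg tables would
require the original simulations and are out of reach by design.

## Numerical choices and problem sizes

Coordinates are always ångström internally (nm inputs scaled ×10 at
load).  PDB round-trips are exact to the format's 0.001 Å field.  Altloc
resolution keeps the highest occupancy, ties to altloc "A".  Rigid-motion
invariance is asserted to 1e-6 Å; the Kabsch result is cross-checked
against an independent rotation-grid refinement oracle to 1e-3 Å on small
point sets.  Stochastic recovery tests use 4000–5000 frames on 12-residue
toys, where the √(2n) sampling error of an RMS sits near 1%, leaving a
5% tolerance at the aggregate level (individual atoms get 10%, since the
six rigid degrees of freedom absorbed by alignment bias single-atom
fluctuations by a few percent).  Clustering recovery uses well-separated
three-component mixtures of 240–300 points with component means asserted
to 0.1.  These sizes were chosen as the smallest at which the statistical
tolerances are comfortably meaningful.

## Limitations

- XTC trajectories are not read (no R-side reader; convert to DCD or
  multi-model PDB).  mmCIF, insertion codes and multi-chain assemblies
  beyond simple chain filtering are out of scope.
- Contact geometry omits face/edge π-stacking classification, halogen
  bonds and metal coordination; water bridges are off unless explicit
  waters exist.
- The rubric is a fixed decision tree, not a calibrated classifier: it
  reproduces the published labels under the default thresholds but has
  no probabilistic interpretation, and thresholds fitted on fifteen
  systems should be re-examined before use on a different target.
- Dual-pose ambiguity in docking (two plausible poses of one compound)
  must be handled by triaging both poses as separate systems; the
  package does not automate pose selection.
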