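---
title: "Methods: field-based 3D-QSAR and docking-pose assessment in mifqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: field-based 3D-QSAR and docking-pose assessment in mifqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifqsar)
```

## The problem

Field-based (CoMFA-style) 3D-QSAR regresses the activity of a series of
aligned small molecules — here pKi = −log Ki values of congeneric ligands
such as synthetic cathinones acting at serotonin receptors — on the
interaction energies a probe pseudo-atom feels at every point of a regular
lattice surrounding the series. Because the descriptors live on a grid,
the fitted coefficients can be projected back into space and contoured,
turning a regression model into a 3-D map of where bulk or charge helps or
hurts binding.

Two ingredients precede the regression and are part of this package. First,
the alignment itself: when no crystal structure of the modelled ligands
exists, poses come from docking, and the trustworthiness of a docking
protocol is quantified before it is trusted. Second, the descriptor matrix
is pathological out of the box (columns spanning twelve orders of
magnitude, most of them constant) and needs a disciplined pretreatment and
variable-selection chain.

## Docking-pose assessment

Pose quality is the heavy-atom RMSD between a docked candidate and the
reference conformation, measured **in place** (no superposition): docked
poses share the receptor frame, and superimposing them would hide exactly
the placement error being measured. Hydrogens are excluded.

A pose with RMSD ≤ a is *docked*, between a and b *partially docked*, above
b *mis-docked*; the defaults a = 2 Å, b = 3 Å follow common practice. The
docking accuracy of an engine over a set of complexes is

DA = f(≤ a) + 0.5 · ( f(≤ b) − f(≤ a) ),

the fraction of correctly docked poses plus half credit for the partially
docked ones. Threshold comparisons are inclusive (≤) by default; a
`strict` reading is available through `da_params(inclusive = FALSE)`, and
no value in the shipped benchmark fixtures falls exactly on a threshold,
so both readings agree there.

The assessment harness runs four stages of increasing difficulty —
re-docking or cross-docking, from the experimental or from a randomized
starting conformation (ECRD, RCRD, ECCD, RCCD) — around *external* docking
engines. The engines themselves are out of scope: the harness consumes
their ranked pose sets. Per complex the engine's **top-ranked** pose is
scored, not the minimum-RMSD pose; DA is meant to measure the scoring
function's ability to recognise the right pose, and min-RMSD selection
(available as `pose_selection = "min_rmsd"`) would inflate it.
`randomize_conformation` provides the randomized starting structures:
centring at the origin, a uniform random rotation, and — when rotatable
bonds are annotated — uniform torsion resampling under a hard-sphere clash
rejection (non-bonded heavy-atom pairs closer than 0.7 × the sum of their
van der Waals radii are rejected and resampled). A force-field
minimisation of the randomized conformer is deliberately not attempted;
the requirement is only a randomized, physically plausible starting point.

Two RCCD benchmark tables for serotonin-receptor ligand sets (14 and 11
complexes × 9 engine/scoring-function columns) ship as plain-CSV fixtures
in `inst/extdata/` and anchor the regression tests of the DA statistic.

## Molecular interaction fields

For every molecule, probe and lattice point the package evaluates

* steric: a 12-6 Lennard-Jones potential in the ε/Rmin parameterization,
  E = Σᵢ εᵢⱼ [ (Rminᵢⱼ/r)¹² − 2 (Rminᵢⱼ/r)⁶ ], with Lorentz–Berthelot
  combination Rminᵢⱼ = Rmin/2ᵢ + Rmin/2_probe and εᵢⱼ = √(εᵢ ε_probe);
* electrostatic: Coulomb, E = Σᵢ 332.0636 qᵢ q_probe / (ε(r) · r) kcal/mol
  with r in Å, under a constant dielectric ε = 1 (default) or the
  distance-dependent ε = r.

Distances below 0.01 Å are clamped to 0.01 Å. These functional forms and
the built-in probe table (eight probes: CR, CB, NC=O, NR, O=C, OH2, HNCO
and the bare-charge ELE probe; AMBER-style per-element Rmin/2 and ε, a
TIP3P-like water oxygen for OH2) are declared package defaults — every
parameter is overridable through `probe_spec()` and the `vdw` argument.
No energy cutoff is applied at field time: clamping belongs to
pretreatment, which keeps the raw fields reusable across cutoff scans.

The lattice covers all heavy atoms of the series plus a margin (default
5 Å, a conventional choice) at a grid spacing of 1 Å by default. Points
are linearized x-fastest, `i = ix + nx·(iy + ny·iz)`; the cube and
OpenDX writers convert to their native z-fastest order, and cube files are
written in Bohr as that format expects.

## Pretreatment and its optimization

The operator order is fixed and idempotent: energy **cutoff** (clamp to
±CO kcal/mol; default 5), **zeroing** (|x| < Z → 0; default 0.01), and a
**minimum-SD filter** (drop columns with sample SD < SD; default 0.05,
which also removes near-constant discrete columns). The filter mask is
part of the fitted pretreatment: it is frozen on the training set and
re-applied to any prediction set, so no information leaks from external
compounds, and dropped columns re-enter coefficient maps as zeros.

`vpo_search` grid-searches (CO, Z, SD) against cross-validated q². The
default grid scans CO ∈ {1,…,5} kcal/mol, Z ∈ {0.005,…,0.05} in steps of
0.005 and SD ∈ {0.01,…,0.1} in steps of 0.01 — positive values only:
negative clamps or thresholds are undefined for symmetric operators, so
the scan is anchored at the printed upper bounds and step sizes of the
conventional protocol. Ties break toward smaller CO, then smaller Z, then
larger SD (the sparser model); a triple that empties the matrix is scored
−∞ rather than aborting the scan. Variable selection (FFD) runs once,
after the pretreatment optimum is fixed — not inside every grid point —
which keeps the scan affordable and the selection interpretable.

## PLS and the validation battery

The regression core is NIPALS partial least squares with mean-centering of
X and y and **no column autoscaling** — the CoMFA convention, since all
field columns share the kcal/mol scale and autoscaling would inflate noise
points. Components (at most 5) are extracted by deflation, so models for
1…k components are nested and returned together; at full rank the model
coincides with ordinary least squares, one of the identities the test
suite checks, alongside an algorithmically independent Krylov-subspace
oracle for the coefficients.

Validation follows the standard battery:

* **q² (LOO / LSO)** = 1 − PRESS / Σ(y − ȳ)², with the full-sample mean in
  the denominator and every fold refitted from scratch on the frozen
  descriptor set. LSO uses 5 random groups and averages over 20 random
  partitions by default (the partition count is a package choice, recorded
  with its seed in every report). SDEP = √(PRESS/n).
* The reported component count is the argmax of LOO q² over 1…5.
* **Y-scrambling** (default 100 permutations) permutes activities, refits,
  and averages r², q²_LOO and q²_LSO. FFD is not re-run inside the
  scramble: the scrambled statistics then bound the selection bias of the
  fixed descriptor set, at a fraction of the cost.
* **External prediction** reports per-compound absolute errors (AEP),
  their mean (AAEP) and q²_pred = 1 − Σ(ŷ−y)² / Σ(y−ȳ_TR)², whose
  denominator is anchored on the **training** mean — the conservative
  convention for predictive q².

**FFD variable selection** follows the GOLPE idea: a two-level design over
the real columns plus ~20% inert dummy variables, about twice as many
design rows as variables, one cross-validated SDEP per row. A variable's
effect is mean SDEP(excluded) − mean SDEP(included); the dummy effects
estimate pure design noise. Variables whose effect exceeds the dummy mean
+ 2 SD are clearly helpful and kept; those below the dummy mean − 2 SD are
detrimental and dropped. Variables inside the noise band are *uncertain*,
and the package drops them by default (`keep_uncertain = FALSE`): on field
matrices the uncertain class is dominated by grid points carrying no
signal, and retaining them (the permissive GOLPE option, available via
`keep_uncertain = TRUE`) defeats the purpose of the selection. Both modes
are exercised in the tests.

## The synthetic-data generator

Real training sets for this workflow require docked ligand conformations
inside experimentally solved receptors, which cannot be bundled. The
generator instead builds the statistical object the models assume, with a
known ground truth:

* `make_aligned_series()` — a rigid ~10-heavy-atom scaffold (ring plus
  amino-ketone tail) with identical coordinates across the series
  (pre-aligned by construction), plus single-atom pseudo-substituents at
  fixed attachment sites arranged as octahedron vertices ≥ 6.5 Å apart.
  Substituents draw an element from {C, N, O, F, Br} (varying the van der
  Waals radius) and a charge uniform in [−0.5, 0.5]. Single atoms keep
  every site's field contribution governed by one latent factor per field
  kind, which is what makes recovery provable; chemical realism of the
  substituents is not the goal.
* `plant_activity()` — computes the fields, plants ±effect weights on
  selected columns, scales the noiseless signal into the pKi window
  4.2–6.0 (the span typical of cathinone training sets, so error metrics
  are commensurate with practice) and adds Gaussian noise **in pKi units**
  after scaling, so `noise_sd` compares directly with AAEP. Planted
  columns must survive the default pretreatment (|x| ≤ 5 kcal/mol,
  SD ≥ 0.1), and at most one weight is planted per (site, field-kind)
  bucket: columns around one site are near-collinear images of that
  site's factor, and planting opposing weights on one factor would cancel
  unidentifiably — the ground truth would be unrecoverable by *any*
  method, which would make recovery tests vacuous.
* `perturb_pose()` — poses at an exactly controlled heavy-atom RMSD
  (rigid translation, or per-atom Gaussian displacement rescaled to the
  target), exercising the DA harness end to end without a docking engine.

What passing these tests shows — and what it does not: the synthetic
series has a rigid shared scaffold, uncorrelated single-atom substituents
and exactly linear field–activity structure. Real docked series add
alignment noise, conformational flexibility, correlated substitution
patterns and non-linear effects; recovery on the generator therefore
validates the machinery (fields, pretreatment, PLS, validation statistics,
maps), not the chemistry of any particular real dataset. On the electrostatic
side, clamp-saturated columns (points where the Coulomb term rails against
the cutoff for every molecule) act as high-variance distractors in
BOTH-field models, which is why steric-only models score higher on the
generator — the same ordering the workflow's real applications report.

## Numerical choices and degenerate inputs

* NIPALS stops early when the residual weight norm falls below 1e-12
  (matrix deflated to noise); the fitted component count is reported.
* Constant y, fewer than 3 molecules, or more components than
  min(rows − 1, columns) are errors, as are LOO with n < 4 and SD
  filtering with fewer than 2 rows.
* Empty engine pose sets are excluded with a warning; a per-cell
  reference/candidate mismatch is recorded as a missing cell, never
  silently dropped.
* All stochastic stages (LSO partitions, scrambling, FFD design, the
  generators) are pure functions of an integer seed; pipeline stages
  derive per-task seeds from the master seed, so a rerun of
  `run_pipeline()` with one config is bit-identical.
* Problem sizes in the shipped tests are chosen for fast, deterministic
  feedback: series of 12–24 molecules, lattices of a few thousand points,
  10–50 scrambling permutations, 3–20 LSO repeats.

## Worked example

```{r example, eval = FALSE}
ser <- make_aligned_series(n_molecules = 24, n_sites = 3, seed = 11)
pa  <- plant_activity(ser, seed = 12, noise_sd = 0.1)

cfg <- run_config(pa$molecules, pa$activities,
                  probes = "OH2", fields = c("STE", "ELE", "BOTH"),
                  lso_repeats = 20, n_scramble = 100, seed = 42)
run <- run_pipeline(cfg)
print(run)          # Table-7-style statistics: GS, PC, CO, Z, SD, r2, q2 ...
run$maps[["OH2_STE"]]
```

## Known limitations

* No symmetry-corrected RMSD: atom mapping is positional by default; an
  `atom_map` hook accepts an automorphism-aware pairing computed
  elsewhere.
* No directional hydrogen-bond probes, desolvation or entropic terms in
  the fields; no SAMPLS, smart-region definition, BUW block weighting or
  consensus-model merging in the PLS layer.
* Docking engines are external; the package evaluates their output but
  never runs them.
* Charges are read from input (MOL2) or zero-filled — charge assignment
  is upstream work.
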