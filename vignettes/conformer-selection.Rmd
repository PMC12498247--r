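---
title: "Feature-based conformer selection and conformer-weighted descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based conformer selection and conformer-weighted descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confsel)
library(dplyr)
```

## The problem

Molecular feature libraries for catalyst design are usually built from a
single "ground-state" structure per ligand, yet many steric and electronic
descriptors are conformation-dependent.  For bisphosphine-ligated Pd(II)
dichloride complexes the full conformer ensemble of a flexible ligand can
hold tens of structures inside a 5 kcal/mol window, and refining all of them
at the DFT level is prohibitively expensive for library-scale work.  confsel
implements a pragmatic middle road:

1. compute cheap coordinate-based steric/geometric descriptors for every
   conformer of a semiempirical (e.g. CREST/GFN-FF) ensemble;
2. prune the ensemble to at most eleven structures by *equidistant coverage*
   of a chemically meaningful feature axis — by default the bite angle —
   rather than by energy;
3. aggregate per-conformer descriptors into conformer-weighted statistics
   (Boltzmann average, min, max, mean, lowest-energy value);
4. feed the aggregated table into standard small-data modelling workflows
   (forward stepwise MLR; CART regression trees with permutation feature
   importance and cross-validation sweeps).

Quantum-chemical quantities (NPA charges, NMR shifts, orbital energies, bond
occupancies) are *ingested* from CSV property tables, never computed here.

## Descriptors and their conventions

All geometric descriptors are computed from Cartesian coordinates.

* **Bite angle** — the P–Pd–P angle in degrees, from the two phosphorus
  donors nearest the unique Pd.
* **Percent buried volume (%Vbur)** — the fraction of a sphere of radius
  *r* (2–7 Å) about Pd occupied by the ligand's scaled van der Waals
  spheres, integrated on a cubic grid (default spacing 0.05 Å) with a Monte
  Carlo cross-check mode.  Defaults follow common practice where the
  original workflow leaves them unstated: Bondi radii scaled by 1.17 (the
  SambVca convention), hydrogens included, the Pd itself and both chlorides
  excluded so the number characterizes the bisphosphine.  All of these are
  arguments, so a user matching a published library can change them.
* **Equivalent cone angle** — the solid angle Ω subtended at Pd by the
  union of the ligand atoms' van der Waals spheres, measured by
  quasi-uniform ray sampling (Fibonacci lattice, default 10^5 directions),
  reported as the apex angle Θ = 2·acos(1 − Ω/2π) of the equivalent
  circular cone.  An atom sphere containing the apex covers the whole sky
  when clamping is on; with clamping off it is an error.
* **SASA** — Shrake–Rupley style with 960 surface points per atom and a
  1.4 Å probe; "SASA at Pd" is the Pd entry of the per-atom vector.
* **Molecular volume** — the volume of the union of unscaled van der Waals
  spheres on a 0.1 Å grid.
* **Donor roles** — the two phosphorus donors are ranked by the buried
  volume (r = 3.0 Å about Pd) of their own substituent branches.  The
  branch partition is a convention of this package: bonds are perceived
  with covalent radii × 1.2; after removing Pd and the chlorides from the
  graph, each atom is attributed to the phosphorus with the smaller graph
  distance, and atoms equidistant from both donors (shared backbone) count
  with weight 1/2 for each.  Ties in the resulting %Vbur go to the
  lower-indexed phosphorus.

Monte Carlo modes use a fixed default seed (2025) so results are
reproducible by default; grid/MC agreement is part of the test suite.
Descriptors with two symmetric instances (Pd–P and Pd–Cl bond lengths) are
emitted as `_avg`, `_min`, `_max` columns.

Numerical accuracy at the defaults, verified against closed forms in the
tests: single-sphere %Vbur within ~0.02 percentage points; single-sphere
cone angles within ~0.005°; isolated-atom SASA exact up to the lattice
(within 1 %); sphere-union volumes within 1 % of the analytic two-sphere
formula.

## The selection rule

`select_equidistant()` builds `n` (default 10) evenly spaced target values
between the minimum and maximum of the selection feature, then greedily
assigns each target the closest not-yet-chosen conformer; ties go to the
lower energy, then the lower index.  Endpoint targets force the feature
extremes into every selection, so the selected range always equals the full
range on the selection axis.  If the lowest-energy conformer was not picked
it is appended, giving at most `n + 1` structures.  The degenerate case of
an all-constant feature falls back to the `n` lowest-energy conformers with
a warning.  Greedy without-replacement assignment in ascending target order
is this package's convention; the published workflow does not state its tie
rules, and the bookkeeping in the returned object (`targets`,
`lowest_energy_added`) makes the behaviour auditable.

`coverage_metrics()` quantifies what a selection preserves: per feature,
the fraction of the full-ensemble range spanned by the selected conformers
(1 by convention when the full range is degenerate).  Energy-based
selection systematically under-covers features uncorrelated with energy;
the acceptance script measures this on synthetic ensembles.

The default `n = 10` mirrors the "up to ten plus the lowest-energy
conformer" working point; `n = 5` is supported but under-represents larger
ensembles.

## Boltzmann weighting and aggregation

Weights are `w_i = exp(-(E_i - E_min)/RT) / Z` with `R = 1.987204e-3`
kcal/(mol·K) and `T = 298.15 K` by default (the energy shift is purely for
numerical stability).  `aggregate_features()` produces the five statistics
per feature — Boltzmann average, min, max, arithmetic mean, lowest-energy
value — which is the expansion that turns a per-conformer descriptor
vocabulary into a conformer-weighted feature library.  Features missing in
some conformers are aggregated over the present subset with re-normalized
weights and a warning.

`variance_filter()` drops the redundant statistics of
conformation-insensitive features: per feature the dispersion is the
maximum over ligands of `(max - min) / max(|mean|, eps)`, and features
below the threshold (default 0.01) keep only the Boltzmann average.  The
threshold that produced the published feature counts is not documented, so
it is an argument and the filter reports exactly how many columns survive.
`compare_sets()` implements the companion diagnostic — mean absolute
percent difference (with the reference set in the denominator, near-zero
references dropped and counted) plus an OLS slope/intercept/R² per feature
— for judging whether a cheaper level of theory is adequate for a given
descriptor class.

## Modelling workflows

Two small-data workflows consume the aggregated table:

* **Forward stepwise MLR** (`forward_stepwise_mlr()`): features are
  z-scored with training-set statistics only; the greedy search adds the
  feature maximizing training R² (a leave-one-out R² scorer is available;
  LOO-R² also breaks ties), skipping candidates that push the design
  matrix's condition number above 1e8; the final model is an ordinary
  least-squares fit.  Reports carry train/test R², MAE and RMSE plus
  per-ligand absolute errors — the numeric content of a prediction-error
  distribution plot (`error_distribution()`, `error_quantiles()`).
* **Decision-tree regression** (`fit_tree()`): CART variance-reduction
  splits via rpart with complexity pruning disabled, controlled by
  `max_depth` and `min_leaf` (tuned by 5-fold CV MAE over a small grid in
  `tune_tree()`).  `permutation_importance()` measures the test-set RMSE
  increase when one feature column is shuffled (seeded, averaged over
  repeats) and `reduce_by_importance()` keeps the top-k features — k = 4
  mirrors the published reduction, and importance measured on the test
  split is deliberately reproduced as-is, leakage and all, because that is
  the workflow being emulated.
* **Cross-validation** (`cross_validate()`): leave-one-out (pooled
  predictions scored once), k-fold (default 5; 42 ligands split 9/9/8/8/8),
  repeated random splits at a fixed test ratio (default 100 starts), and a
  test-ratio sweep over 0.1–0.5 in 0.1 steps.  Feature selection is redone
  inside every training split.

MAE ≤ RMSE holds for every report (Jensen), and stepwise training R² is
non-decreasing in the number of terms; both are tested properties.

## The synthetic generator

Real ensembles require external conformer searches, so the package ships a
generator that emulates their statistical shape without any chemistry:

* `make_complex()` builds an idealized square-planar PdCl2(P^P) core with
  an exactly prescribed bite angle, Pd–P/Pd–Cl distances, and single-atom
  dummy substituents (spheres are all the descriptors need); equal
  substituent patterns give an exactly C2-symmetric complex.
* `make_ensemble()` draws bite angles from a normal distribution, jitters
  the substituents (0.05 Å), and assigns pseudo-energies either independent
  of geometry (uniform in the 5 kcal/mol window) or linear in bite angle
  with noise, rescaled into the window.  Everything is deterministic given
  the seed.
* `make_dataset()` plants a known response rule on aggregated statistics:
  per ligand a small ensemble (8–20 conformers) receives pseudo-electronic
  conformer-level features with ligand means from N(0,1) and conformer
  spreads drawn from 0.2–0.8, and `y` follows a stated linear rule on named
  statistics (e.g. `2·max(f1) − max(f2)`) plus 0.3 kcal/mol noise.  The
  defaults — 42 ligands, 33:9 train/test splits in the tests — mirror the
  size regime of the carbonylation case study; responses keyed to ensemble
  *maxima* make a lowest-energy-only featurization provably lossy, which is
  the mechanism the package exists to expose.

What the generator does *not* emulate: real rotamer multi-modality,
correlated feature noise, force-field artefacts, or oxidation/curation
issues in real datasets.  Passing tests therefore demonstrate the
correctness of the algorithms and the direction of the
conformer-information effect, not the numeric performance obtainable on any
real reaction dataset.

Coverage sweeps in the tests use ensembles of 20–60 conformers — larger
than the selection budget of eleven — because pruning is only meaningful in
that regime; ensembles at or below the budget are returned whole.

## Numerical and design choices

* Energies are kcal/mol internally; Hartree input is converted on read
  (× 627.5094740631).  XYZ comment-line energies default to
  "first floating-point token", with a `key=value` dialect available,
  since conformer-search drivers disagree on the format.
* Atom indices are 1-based everywhere in R surfaces and reports.
* The temperature default is 298.15 K; workflows quoting "298 K" exactly
  can pass `temperature = 298`.
* Degenerate inputs are contracts, not crashes: zero-variance responses
  yield `NA` R² with a warning; a constant training response or
  `max_depth = 0` gives a single-leaf tree; an empty included-atom set
  gives 0 %Vbur with a warning; an all-constant selection feature falls
  back to energy ordering.
* Problem sizes in the test-suite (grid spacings of 0.08–0.2 Å for batch
  descriptor tests, 20 modelling replicates, 100-ensemble coverage sweeps)
  were chosen so the whole suite runs in a few minutes on one CPU while
  keeping every estimator inside its stated tolerance; the
  single-descriptor accuracy checks always run at the production defaults.

## Known limitations

* No bond-order or valence model: bond perception is a covalent-radius
  cutoff, adequate for branch partition but not for general chemistry.
* Solid angles are sampled, not computed by exact sphere-union analytics;
  accuracy is set by the ray count.
* Only single-energy Boltzmann weighting is provided (no entropy-corrected
  free energies).
* SHAP-style attributions are out of scope; permutation importance is the
  implemented importance metric.
* The 2088/1300-style feature counts of a production library depend on
  descriptors (free-ligand properties, wavefunction-derived quantities)
  this package ingests rather than computes, so feature counts here are
  always fixture-relative.

## A worked micro-example

```{r example}
ens <- make_ensemble(ensemble_spec(n_conformers = 30, seed = 1),
                     ligand_id = "demo")
feats <- describe_ensemble(ens, features = "geometry")
sel <- select_conformers(ens, by = "bite_angle", features = feats, n = 10)
glance(sel$selection)
coverage_metrics(sel$selection, feats) |>
  filter(feature %in% c("bite_angle"))
agg <- aggregate_ensemble(ens, records = feats)
head(agg, 3)
```
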