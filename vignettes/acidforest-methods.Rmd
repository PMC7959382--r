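---
title: "Predicting milk acidification rates from genome content: models and methods"
author: "acidforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting milk acidification rates from genome content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidforest)
```

## The problem

Dairy *Lactococcus lactis* starter strains differ widely in how fast they
acidify milk. The phenotype of interest is the **maximum hourly
acidification rate** `Vmax` (pH·h⁻¹): the most negative slope of the milk pH
curve over a sliding ~1-hour window. Because the pH drops during
fermentation, `Vmax` is negative and *more negative means faster
acidification*. Strains are assayed under 12 condition combinations —
temperature (25/30/40 °C) × culture volume (lowwell 200 µl / deepwell
2000 µl) × yeast-extract supplementation (±0.2%) — and the task is to
predict `Vmax` from genome content plus the assay conditions, and then to
ask *which* genomic features drive the prediction.

`acidforest` implements this pipeline end to end:

1. **Kinetics** — hue→pH calibration and sliding-window `Vmax` extraction.
2. **Featurization** — four genomic representations: gene presence/absence
   (Roary-style pangenome tables), Pfam domain copy numbers
   (pfam_scan-style hit tables), and canonical 8-mer / 9-mer counts from
   assemblies; each pruned and collapsed.
3. **Modelling** — strain-level 75/25 split, random-forest regression with
   a published hyperparameter grid and per-representation presets,
   PC/EV/RMSE evaluation.
4. **Signal tests** — two permutation schemes quantifying how much of the
   model's accuracy comes from the genome rather than the assay conditions,
   plus training-size learning curves.
5. **Importance** — exact TreeSHAP attribution, k-mer→gene and domain→gene
   resolution, and a cross-representation consensus report.
6. **Synthetic data** — a clade-structured population generator with
   planted causal loci, so every stage is testable without external data.

## Vmax extraction

pH is recorded every 6 minutes (0.1 h). For every contiguous window of 10
measurements (spanning 54 min) we compute the **ordinary least-squares
slope** in pH·h⁻¹ and return the most negative one; a curve with no
negative window slope yields 0.

Two operational choices deserve note, both exposed as parameters:

* *Slope estimator.* The window slope could be the OLS regression slope or
  the endpoint difference. We default to OLS because it is robust to
  single-point noise; the two coincide exactly on linear (and quadratic)
  stretches, which is where `Vmax` typically lives. `method = "endpoint"`
  switches the estimator.
* *Window length.* "One hour" at 6-minute sampling can be read as 10 or 11
  points; we take `windowPoints = 10` literally and make it a parameter.

Scanner output is hue, not pH. `fitHueCalibration()` fits a degree-4
polynomial pH(hue) by least squares to calibration pairs spanning roughly
pH 6.5–4.0. Monotonicity over the fitted hue range is checked numerically
on a 512-point grid; a non-monotone fit **warns** rather than fails,
because real dye responses can wiggle at the edges of the usable range,
and a constant fit counts as trivially monotone. Conversion outside the
fitted hue range is polynomial extrapolation and is flagged per point.

## Feature representations

* **Canonical k-mers.** A k-mer and its reverse complement are one
  feature, represented by whichever string sorts first alphabetically.
  Windows containing ambiguous bases are skipped and windows never span
  contig boundaries. There are 4⁹/2 = 131072 canonical 9-mers and
  (4⁸−4⁴)/2+4⁴ = 32896 canonical 8-mers (even k admits palindromes); both
  counts are verified by exhaustive enumeration in the test suite. Raw
  per-window counting is delegated to `Biostrings::oligonucleotideFrequency`;
  the canonicalization is this package's own.
* **Gene presence/absence.** Any non-empty strain cell of a Roary-style
  table (including multi-locus paralog cells) codes as 1.
* **Pfam domains.** Copy numbers: the number of hits of an accession
  (version retained, e.g. `PF02502.13`) across all genes of a strain.
* **Pruning.** A feature present in *strictly more than* 98% of strains,
  or absent in strictly more than 98%, is removed. At n = 100 this removes
  a feature present in 99 strains and keeps one present in 98 — the strict
  inequality is deliberate and tested. "Present" means value > 0 for
  count-valued features.
* **Collapsing.** Features with identical value profiles across all
  strains (always co-occurring, e.g. operon members) merge into one column
  named by comma-joining the ids in stable input order. We prune first and
  collapse second; on binary matrices the two orders commute (tested), so
  the choice is cosmetic.
* **Conditions.** Temperature enters as a single numeric predictor
  (25/30/40) rather than one-hot; volume (deepwell = 1) and yeast
  (added = 1) are binary. Predictor columns are sorted by name before
  fitting so column order can never change a fit.

`pangenomeSummary()` classifies gene families by presence fraction p:
core p ≥ 0.99, soft core 0.95 ≤ p < 0.99, shell 0.15 ≤ p < 0.95, cloud
p < 0.15; exact boundaries go to the higher category.

## Random-forest models

The regressor is a `ranger` forest configured to match the published
protocol: **all features considered at every split** (no per-split feature
subsampling — the data are wide and noisy, and this mirrors the reference
implementation's default for regression), bootstrap sampling with
replacement, and a fixed seed. The published candidate grid is shipped
verbatim — trees {10, 50, …, 750}, depth {unlimited, 10, …, 150}, minimum
samples to split {2, 4, …, 16}, minimum leaf size {1, …, 9}, OOB scoring
{on, off}; 36864 combinations — and explored by randomized draws under
3-fold cross-validation on training rows, scored by held-out R² (the
reference library's default regression score; the source protocol does not
state one). The published per-representation optima are available as
`presetParams()` so the expensive search can be skipped.

Splitting is at **strain level** (all 12 measurements of a strain fall on
one side) with |train| = ⌈0.75·n⌉, which reproduces the published 257/85
partition of 342 strains; ⌊·⌋ would give 256/86. Rows with missing `Vmax`
are dropped after splitting, so per-side row counts vary slightly with the
missing pattern. Strain leakage is asserted on every evaluation.

Default seeds (split = 1, search = 1, forest = 1) are arbitrary and
overridable; the source protocol's seeds are unknown, so published
correlations are reproducible only up to split variability (about ±0.05).

## Permutation tests of genomic reliance

Both tests ask whether the model's test-set Pearson correlation depends on
the genome or only on the condition features:

* **Feature permutation** — per replicate, every genomic feature column is
  independently permuted across test *strains* (each strain keeps one
  value per feature, broadcast to its condition rows).
* **Profile switch** — per replicate, one permutation reassigns whole
  genomic profiles among strains, preserving between-feature structure.

Permutation operates at strain level because row-level shuffling would mix
several genomes within one strain. Targets and condition features are
never touched. The 95% interval is the empirical 2.5th/97.5th percentile
of the null correlations (the source describes a "95% confidence interval"
without a formula). We interpret the published feature test as one joint
destruction of all columns per replicate — its single null histogram per
model supports that reading — rather than separate per-feature tests.

## TreeSHAP importance

No SHAP implementation exists in this R stack, so the package implements
**path-dependent TreeSHAP** (exact Shapley values of the conditional-
expectation game on each tree, cover-weighted on off-coalition branches)
in C++ over the flattened `ranger` trees. Per-node covers are computed by
routing the training rows through each tree at training time and stored in
the `ModelBundle`. Two properties anchor correctness in the test suite:
local accuracy (base value + row sum of SHAP = prediction, to machine
precision) and agreement with an exhaustive-subset Shapley oracle on small
forests (tolerance 1e-10).

Because `Vmax` is negative, a **negative SHAP value pushes toward faster
acidification**; importance tables carry an explicit `"faster"/"slower"`
direction label (the sign of the feature-value/SHAP correlation) to avoid
sign confusion. SHAP is computed on test rows, as in the source protocol.
TreeSHAP cost grows as rows × trees × leaves × depth², so
`computeImportances()` can explain a seeded row subsample (`nRows`,
default 150 in the pipeline); mean |SHAP| rankings stabilize well below
that.

k-mers resolve to genes by exact two-strand substring search with a
reporting threshold of >40 carrier strains, domains by hit-table lookup
with a >10 occurrence threshold (both configurable; the defaults follow
the published reporting rules). The consensus report expands collapsed
ids, resolves features to gene labels, and flags entities supported by ≥2
representations.

## The synthetic population generator

The generator emulates the study design: two clades standing in for the
*lactis* / *cremoris* subspecies (clade A fraction 0.67 ≈ 230/342), 12
fixed conditions, planted causal blocks, and measurement noise.

* **Gene content.** Core families in every strain; accessory families
  Bernoulli per clade (defaults A 0.65 / B 0.25, giving the clade-
  structured presence profiles that make hierarchical clustering separate
  the clades); causal blocks drawn per clade with all member genes
  co-occurring, like operons.
* **Sequences.** One i.i.d.-uniform reference per family; carriers receive
  0.5% per-base substitutions; planted 9-mer tags are kept mutation-free,
  are guaranteed absent from every non-causal sequence, and mutants that
  would spawn a foreign tag are redrawn. This preserves k-mer
  detectability while producing realistic near-duplicate features. Note a
  consequence: per-strain substitutions are phylogenetically unstructured,
  so k-mer profiles rarely collapse, and the synthetic k-mer feature space
  (~10⁵ columns at default scale) is much larger than a clonal pangenome's
  (~10⁴ after collapsing in the real data). The package therefore runs its
  k-mer demonstrations at reduced population scale (below).
* **Phenotype.** Internally a positive "speed": b0 + Σ block effects +
  temperature effect (per clade) + yeast effect + 40 °C×yeast rescue (per
  clade; defaults make 30 °C optimal for both clades while only clade A
  benefits from yeast at 40 °C) + volume effect + Gaussian noise, clipped
  to [0.05, 0.96] and negated, so emitted `Vmax` lies within the
  empirically observed [−0.96, −0.05] h⁻¹. Defaults: b0 = 0.35, yeast
  +0.10, deepwell +0.05, two causal blocks of +0.15 h⁻¹, noise SD 0.03,
  19% of measurements missing completely at random (the observed missing
  fraction; the true missingness mechanism is not documented, so MCAR is
  the neutral choice).
* **Curves.** For each target `Vmax` a logistic pH decline from 6.5 to 4.3
  over 12 h is synthesized with steepness solved by root finding so the
  extracted window slope matches the target; hue variants invert the
  built-in monotone calibration. This closes the loop: curve synthesis →
  `computeVmax` → phenotype table reproduces the targets to ≲1%.
* **Determinism.** One master seed drives everything; identical configs
  give byte-identical FASTA and matrices.

What the generator does **not** model: phylogenetic sequence evolution,
recombination, plasmids, assembly artifacts, non-random missingness, and
genuinely correlated effect architectures. Passing tests on synthetic data
therefore demonstrate pipeline correctness (signal recovery, calibrated
nulls, format round-trips), not predictive performance on real strain
collections.

## Problem sizes and numerical choices

* The default synthetic population uses 200 strains with 150 core + 100
  accessory families of 240–600 bp — a deliberately scaled-down pangenome
  (real genomes carry ~2000+ genes of ~1 kb) chosen so the full pipeline
  runs in seconds-to-minutes while preserving the feature-to-sample-size
  imbalance that makes the problem interesting.
* The acceptance script runs gene and Pfam models at that default scale
  with 200 permutation replicates per test, and the two k-mer models on a
  reduced population (60 strains, 50 families of 100–200 bp), reflecting
  the k-mer feature-space blow-up described above; the published protocol
  itself skipped the permutation tests for k-mer models as too heavy.
* Null-calibration experiments use zero-effect blocks **and clade-
  symmetric condition effects**: with clade-specific temperature
  responses, clade-correlated accessory genes would carry genuine
  phenotype signal and the permutation tests would (correctly) reject —
  the null scenario must sever every genome→phenotype path.
* Curve-steepness root finding brackets r ∈ [10⁻⁴, 200] with tolerance
  1e-9; targets steeper than the bracket's reach (≈3.3 pH·h⁻¹ for the
  default pH span) are an error.
* The calibration inverse for hue synthesis uses an 8192-point monotone
  grid with linear interpolation (error far below the 2% round-trip
  tolerance); `phToHue()` refines with bracketed root finding to 1e-10.
* Ties and degenerate cases: a flat curve yields `Vmax` 0; an empty hue
  series converts to an empty pH series; collapsing keeps first-occurrence
  column order; `sort(..., method = "radix")` is used wherever name order
  matters so results do not depend on the locale.

## Known limitations

* Published-scale reproduction requires the deposited supplementary
  matrices (not redistributable here); `reproducePublishedModels()` runs
  the full printed protocol once they are placed in a directory.
* Path-dependent TreeSHAP attributes with respect to training-cover
  expectations; interventional SHAP (against an explicit background
  sample) is not implemented. The explainer choice is recorded in the
  importance table's metadata story above.
* Importance dilution among correlated features (a known caveat of SHAP on
  collinear genomic data) is not corrected; the consensus-across-
  representations report is the mitigation.
* The hue model is a single global calibration; per-plate or drift
  corrections are out of scope.
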