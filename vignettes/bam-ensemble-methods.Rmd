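---
title: "Methods: ensemble niche models and BAM set algebra for symbiont-host pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble niche models and BAM set algebra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package asks a biogeographic question about a symbiont that depends on a
host: where is the symbiont limited by its own climatic tolerance, and where
by host availability?  The BAM framework frames this in set terms.  Let *A*
be the area that is abiotically (climatically) suitable for the symbiont,
*B* the area where the biotic requirement — the host — is available, and *M*
the area accessible by dispersal.  The package makes three standing
assumptions, stated up front because every downstream map inherits them:

1. **M is total.**  No dispersal barriers: `(A ∪ B) ⊂ M`.  This is
   reasonable for invasive species with long human-mediated introduction
   histories, and it is what makes the overlap `A ∩ B` interpretable as the
   potentially occupied area.
2. **B equals the host's abiotically suitable area** (`B = A_H`).  Host
   availability is the only biotic factor modelled.
3. **Climate estimates A.**  The predictor set is climatic; suitability maps
   are climatic-niche projections, not full habitat models.

With both *A* and *B* as binary maps on one lattice, only three
configurations are possible: *B* inside *A*, *A* inside *B*, or partial
overlap.  Two difference areas carry the ecological signal:

* `g_bi = A \ B`: climatically suitable for the symbiont, host absent — the
  symbiont is restricted by host availability there;
* `bi = B \ A`: host present, climate unsuitable — the symbiont is
  restricted by its own climatic tolerance there.

`bam_combine()` computes the decomposition, `area_proportions()` its shares
over `A ∪ B` (equal cell weights, or cosine-latitude weights approximating
equal-area measure without a projection engine), and `diagnose_bam()` maps
the shares onto the three cases.

Because estimated maps are never exactly empty, "empty" is operationalised
as a union share below `epsilon` (default 0.01).  The threshold is a package
construct, exposed in the configuration; two extra labels (`equal`,
`disjoint`) make the diagnosis total on degenerate inputs.

## The estimation workflow

*A* and *B* are estimated independently, by the same ensemble procedure:

1. **Cleaning.**  Invalid coordinates, points on invalid (sea/nodata)
   cells, and within-cell duplicates are dropped (first record kept —
   deterministic without an RNG).  Oversampled regions can be thinned to a
   per-region quota (default: the median regional count), sampled uniformly
   under a seed.
2. **Collinearity screen.**  Pairwise Pearson |r| of the predictors at the
   occurrence cells must stay below 0.7 or the run aborts — correlated
   predictors destabilise both the coefficients and the projections.
3. **Pseudo-absences.**  True absences are unreliable for low-prevalence
   symbionts, so each replicate samples background cells instead: as many
   as there are presences, uniformly without replacement over all valid
   non-presence cells, at cell centers.  No exclusion buffer is applied
   around presences.
4. **Replicate design.**  For each of `n_pa_sets` (default 10)
   pseudo-absence selections and `n_reps` (default 10) 70/30
   calibration/test splits (stratified by label; `round(0.7 n)` per class),
   each of the eight model families is fitted on the calibration records
   and projected — 800 individual projections under the defaults.  Failed
   fits are flagged and excluded, never fatal.
5. **AUC-weighted ensembles.**  Within each (pseudo-absence set,
   repetition) group the member projections are averaged with weights
   `w_i = AUC_i / Σ AUC_j`, using each member's held-out test AUC; members
   at AUC ≤ 0.5 carry no ranking signal and are dropped.  This yields 100
   ensemble projections.
6. **Consensus and uncertainty.**  The per-cell mean of the ensembles is
   the species' consensus suitability map; their per-cell sample (n−1)
   standard deviation is the uncertainty map.  Disagreement concentrates
   near range boundaries, which is exactly where the difference areas
   `g_bi`/`bi` live — so the SD map should always be read next to them.
7. **Binarisation.**  Each ensemble's threshold maximises sensitivity +
   specificity on its own held-out test records, scored by the same
   weighted average; candidates are midpoints between adjacent distinct
   scores plus outer sentinels, ties broken toward the smallest maximiser.
   The per-ensemble thresholds are averaged into one consensus threshold
   per species, and the consensus map is cut at it (`value ≥ threshold` is
   presence).

Model skill is summarised three ways, mirroring standard practice:
per-predictor binomial-logit GLMs on occurrences versus one pseudo-absence
selection (`fit_binomial_glm()`, IRLS to a deviance tolerance of 1e-8,
with the chi-square goodness-of-fit tail on the residual deviance); the
rank-based (Mann-Whitney, midrank ties) test AUC of every run; and a
fractional-logit GLM of AUC on algorithm type (`algorithm_effect_glm()`),
whose explained deviance measures how much the choice of family matters.
AUC values are proportions in (0, 1), not integer trials, so the
algorithm-effect model uses quasi-likelihood estimation (identical point
estimates to binomial; z statistics reported on dispersion 1).

### The eight families

The family registry (`model_families()`) treats each algorithm as an
exchangeable calibrated scorer: fit on labelled records, return presence
probabilities.  GLM is logistic regression with linear and quadratic terms
(quadratic terms make Gaussian-shaped responses representable); GAM uses
thin-plate smooths (`mgcv`, k = 4); GBM is gradient-boosted trees
(`xgboost`, depth 3, eta 0.1, 40 rounds); ANN a single-hidden-layer
network (`nnet`, 4 units, decay 0.01, standardised inputs); CTA a
classification tree (`rpart`); RF a probability forest (`ranger`, 100
trees).  Two families are implemented as nearest equivalents under the
same id: **FDA** as quadratic discriminant posteriors (`MASS::qda`) —
flexible discriminant analysis is discriminant analysis in a nonlinear
basis, and a quadratic boundary is the minimal flexible form able to
enclose a band-shaped niche; **MARS** as logistic regression on natural
cubic spline bases (`splines::ns`, df 3 per predictor) — fixed-knot rather
than adaptive-knot regression splines.  Hyperparameters are frozen in the
registry; the ensemble weighting, not tuning, is the mechanism that
rewards better members.

### Seeds

Every stochastic step takes an explicit seed, derived from one master seed
and the (pseudo-absence set, repetition, family) indices by a small
counter-based hash, so replicate streams are independent and a rerun with
the same master seed reproduces every AUC and map bit for bit.  RNG state
of the calling session is always restored.

## The virtual-species generator

The generator exists so the whole chain — cleaning to diagnosis — can be
validated against known truth without any data downloads.

`generate_climate_stack()` produces four spatially autocorrelated fields
(box-smoothed Gaussian noise, half-width 3 cells) with weak, distinct
large-scale gradients and realistic ranges: minimum winter temperature
(latitudinal), maximum summer temperature (weakly latitudinal), annual
precipitation (longitudinal, mm), and precipitation seasonality (CV %, no
gradient).  Gradients are kept small relative to the smoothed noise so
that layers stay weakly correlated; the stack is regenerated under rotated
seeds until all pairwise |r| ≤ 0.7 — the same screen applied to real
predictors.  Default lattice: 60 × 60 cells of 0.5°.

A `virtual_niche()` is a set of per-predictor responses (Gaussian or
logistic) combined by **product** — limiting-factor logic that keeps
suitability in [0, 1] with an interpretable optimum, rather than an
additive score.  Occurrences are drawn with probability proportional to
suitability, with replacement, at cell centers (duplicates are exactly
what `clean_occurrences()` collapses, so the synthetic data exercises the
cleaning path too).

Two generator defaults deserve their rationale:

* **Prevalence-consistent truth.**  The true binary range defaults to
  `suitability ≥ landscape mean suitability`.  Under uniform background
  sampling, the sensitivity+specificity-optimal ROC cut of an ideal model
  converges to the landscape-mean suitability (the presence and background
  score densities cross there), so truth defined at that level is the
  range an ideal model *binarised by this workflow* would recover.  A
  fixed arbitrary constant instead builds a systematic range-size mismatch
  between truth and estimate that no amount of model skill removes.
* **Learnable breadths.**  Niche breadth along the structuring axis
  defaults to 0.32 (wide) / 0.18 (narrow) of the axis field's standard
  deviation.  For a Gaussian response of breadth *b* on a field of spread
  σ, presences concentrate at axis distance ~ N(0, σ·b/√(σ²+b²)), and the
  AUC of an ideal ranker against uniform background is
  `(2/π)·atan(σ/σ_p)`; breadths at or below ~0.3σ put that ceiling above
  0.8, the performance regime the workflow is meant to operate in.
  Non-axis responses default to very broad (4σ) so the pair's set
  relations are governed by one axis, which keeps the subset
  constructions analytic.

`make_virtual_pair()` realises a chosen true configuration by breadth
nesting (cases 1 and 2: same optimum, wide vs narrow — a narrower Gaussian
lies below a wider one everywhere, so nesting is exact) or optimum
offsetting (case 3: equal breadths ~0.7σ apart).  The realised truth is
always verified through `bam_combine()`/`diagnose_bam()` at epsilon 0.01
and re-jittered until it holds.

What the generator does **not** emulate: sampling bias correlated with
accessibility, spatial clustering of records beyond suitability, predictor
measurement error, interactions between predictors in the niche, and
dispersal limitation.  Passing the recovery experiments therefore shows
the machinery is correct and the inference chain coherent — not that real
occurrence data meet these idealisations.

## Numerical conventions

* Extent bounds are outer cell edges; a cell owns `[edge, edge + res)` on
  both axes, so points on shared edges resolve deterministically
  (lower/left inclusive).  Row 1 is the northernmost row.
* Square cells are enforced; inputs are never resampled or reprojected.
  Equal-area intent is served by cosine-latitude weights.
* Cells exactly at a binarisation threshold count as presence.
* Ensemble SD uses the two-pass sample formula, so identical ensembles
  give an exactly-zero uncertainty map.
* Crop windows snap outward to the lattice; cropping is always an exact
  sub-array.

## Problem sizes

The validation experiments run at desk scale, chosen to exercise the full
design faithfully while staying cheap: the replicate-count and skill
checks use the complete 10 × 8 × 10 design on a 60 × 60 lattice with 150
occurrence draws; the case-recovery experiment uses 3 pseudo-absence sets
× 2 repetitions with a representative parametric / semi-parametric /
tree-ensemble trio (GLM, GAM, RF) per species, over three constructed
cases and multiple seeds.

## Known limitations

* Raster I/O is ESRI ASCII only; GeoTIFF paths raise a clear error.
* `B = A_H` treats the host's *potential* (climatic) area as available —
  the host actually occupies at most a subset of it, so `B` is an upper
  bound on host availability and the overlap an optimistic estimate of
  jointly suitable area.  The package documents this rather than modelling
  the host's realised range.
* The epsilon diagnosis rule is a reproducibility device, not an
  ecological quantity; conclusions near the boundary should be read with
  the SD map and both share weightings in hand.
* Pseudo-absence sampling uses no geographic buffer, matching the
  worldwide-background design; prevalence-dependent thresholds inherit
  that choice.
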