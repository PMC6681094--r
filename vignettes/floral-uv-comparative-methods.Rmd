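---
title: "Phylogenetic comparative methods for floral UV pigmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic comparative methods for floral UV pigmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floraluv)
```

## The problem

Many flowers that look uniformly colored to humans carry an ultraviolet
"bullseye": a UV-absorbing petal base under a UV-reflective apex, visible to
most pollinating insects. The fraction of the petal area that absorbs UV
(the *UV proportion*, UVP, in [0, 1]) varies across species, and in groups
such as Potentilleae (Rosaceae) its distribution is bimodal: one mode at an
intermediate bullseye and one at complete UV absorption. `floraluv`
implements the comparative toolkit needed to ask whether this variation
tracks geography (latitude, altitude) and bioclimate (temperature,
precipitation, UV-B irradiance) once shared evolutionary history is
accounted for.

The analysis is two-staged, mirroring the bimodality of the phenotype:

1. **All species** — UVP is dichotomized at a threshold (default 0.95):
   species with any detectable UV-reflective apex (UVP < 0.95) are
   *patterned*, the rest *uniformly absorbing*. The binary state is tested
   for phylogenetic signal (Pagel's λ) and regressed on geographic and
   bioclimatic predictor sets with phylogenetic generalized estimating
   equations (GEE).
2. **Patterned species only** — quantitative UVP is tested for signal
   (Blomberg's K) and regressed on the same predictor sets by phylogenetic
   least squares (PGLS) under Brownian-motion (BM) and Ornstein–Uhlenbeck
   (OU) residual covariance, with through-origin independent-contrast (PIC)
   regressions as single-predictor summaries.

Every analysis runs over a set of trees standing in for a Bayesian
posterior sample, and results are aggregated as mean, SE and mean P across
trees, so that topological uncertainty propagates into the reported
estimates.

## Models and statistics

**Tip covariance.** For a rooted ultrametric tree, BM predicts tip
covariance equal to shared root-to-ancestor path length. The package also
provides Pagel's λ transform (off-diagonals scaled by λ ∈ [0, 1]), the
unit-branch transform (all branch lengths set to 1; used as the GEE working
correlation), and the fixed-root OU covariance
$V_{ij} = \frac{1}{2\alpha} e^{-\alpha d_{ij}}(1 - e^{-2\alpha t_{ij}})$
with $d_{ij}$ the patristic distance and $t_{ij}$ the shared time from the
root. As α → 0 the OU correlation tends to the BM correlation; this limit
is asserted in the test suite.

**Blomberg's K** compares the observed ratio of tip variance to
phylogenetically corrected variance against its BM expectation; K = 1 under
BM (exactly 1 on a star phylogeny, a property used as an oracle test),
K < 1 means less resemblance among relatives than BM predicts. Significance
comes from a randomization test: the variance of the standardized
independent contrasts is compared with its distribution under tip-label
permutation (999 randomizations by default), with the usual +1 correction,
so the smallest attainable P is 1/(n_reps + 1). Contrasts are linear in the
tip values, so the whole permutation null is a single matrix product.

**Pagel's λ** is estimated by profile maximum likelihood (the phylogenetic
mean and rate are concentrated out analytically). On an ultrametric tree
V(λ) shares the eigenvectors of V, so one symmetric eigendecomposition
makes each profile evaluation O(n); the optimizer is a bounded golden-section
search with 10 equally spaced restarts (tolerance 1e-8) over [0, 1] — the
upper bound is capped at 1, the maximum-feasible value on ultrametric
trees. The test of λ > 0 is a likelihood-ratio test against λ = 0 referred
to χ²₁. Because λ = 0 lies on the boundary of the parameter space this
reference is deliberately conservative (measured size ≈ 0.01–0.03 at
nominal 0.05 in the test suite); a boundary mixture would be less so, but
the χ²₁ convention matches standard practice. Binary 0/1 states are
accepted with a warning: the Gaussian model is misspecified for them, but
treating presence/absence as continuous 0/1 is the established convention
this package reproduces.

**Phylogenetic GEE.** The binary state (pattern present = 0, absent = 1, so
positive coefficients mean "more likely uniformly absorbing") is modeled
with a binomial family, logit link, and working correlation equal to the
unit-branch-tree correlation. The estimating equations
$U(\beta) = D'\Sigma^{-1}(y - \mu) = 0$ are solved in two stages: BFGS
minimization of $\lVert U \rVert^2$ (with analytic gradient) from the
ordinary-GLM start, then Newton polish with the exact Jacobian to
max |Δβ| < 1e-8. Plain Fisher scoring is not used as the outer loop because
with a strong working correlation it can spiral; and because the estimating
equations can admit several roots, the root nearest the GLM solution is
taken (continuity argument: as the working correlation tends to the
identity, the GEE root tends to the GLM fit). Data with no finite root
(separation) are returned with a warning, as `glm` does. Standard errors
are model-based — with a single cluster (one phylogeny) the sandwich
estimator is degenerate — and P-values use a t reference on dfP − k degrees
of freedom, where the *phylogenetic degrees of freedom*
dfP = (total branch length)/(mean root-to-tip depth) of the unit-branch
tree. dfP equals n on a star tree and shrinks as shared history grows; the
formula is validated by closed-form star/cherry/pectinate cases. Model
comparison uses QIC (quasi-likelihood information criterion); under an
identity working correlation QIC reduces exactly to the GLM AIC, another
oracle test.

**PGLS.** Maximum likelihood throughout (not REML), so likelihood-ratio
tests on fixed effects are valid and the BM fit's log-likelihood equals the
λ profile at λ = 1 (asserted to 1e-8). Under OU the selection strength α is
profiled on a 30-point log-spaced grid over [1e-8/T, 50/T] (T = tree
height) and refined by bounded search; the profile curve is kept in the fit
because near-BM data leave the likelihood flat in α, and a point estimate
alone would be misleading there. Coefficient SEs use the n/(n−k)
small-sample scale and t P-values with n − k df. AIC counts k + 1
parameters for BM (coefficients + rate) and one more for α. BM is nested in
OU at α → 0, so AIC(OU) ≤ AIC(BM) + 2 always; the LRT uses χ²₁.

**PIC regression.** Felsenstein's pruning algorithm with through-origin
regression of response contrasts on predictor contrasts (contrasts have
expectation zero, so the intercept is fixed at zero; df = n − 2). Each
contrast pair is oriented so the predictor contrast is non-negative, which
fixes the slope's sign without affecting the fit. The identity between the
through-origin PIC slope and the BM PGLS slope (with intercept) is asserted
to 1e-8 over random instances — the strongest cross-module consistency
check in the suite.

**Predictor standardization.** Before multi-predictor fits, predictors are
centered on their phylogenetic (GLS) mean and divided by the square root of
their evolutionary rate, making coefficients comparable across predictors
with different units. The rate divisor is n − 1 so that on a star tree this
reduces to the ordinary z-score (a config switch gives the ML divisor n).

## Aggregation over trees

`run_across_trees()` prunes each tree to the data's species, runs the
analysis with a per-tree seed (base seed + tree index), records failures
without aborting, and `summarize_across_trees()` reports the arithmetic
mean of estimates, their SE across trees (sd/√m by default; plain sd via a
flag, recorded in the output), and the arithmetic mean of P-values. Mean-P
(rather than Fisher/Stouffer combination) is the reporting convention this
package follows. With identical trees the SE is exactly 0.

## The synthetic study generator

`sim_study_dataset()` emulates the joint structure of a species-level
floral UV survey so every stage is testable without external data. Its
defaults are fixed study conditions, not tuning knobs:

- **Tree**: 177-tip Yule tree of height 30 (a Myr scale consistent with a
  tribe-age calibration of a few tens of Myr); tree sets add node-age
  jitter (lognormal sd 0.1) and 2 NNI moves per tree, then restore exact
  ultrametricity — a stand-in for posterior topological and branch-length
  uncertainty, judged adequate by producing nonzero across-tree SEs.
- **Predictors**: five traits simulated under a λ = 0.5 transform (signal
  present but well below BM, matching the weak K values such surveys
  report), recolored so the realized Pearson correlation matrix equals the
  target exactly (altitude–temperature −0.28, altitude–precipitation −0.21,
  altitude–UV-B +0.84, plus plausible latitude rows), then scaled to
  published means (43.04 °N, 1705 m, 4.89 °C, 729.2 mm, 3003 J m⁻² d⁻¹).
- **Binary state**: a latent liability = logistic linear predictor on
  z-scored bioclimatic predictors (intercept 0.259, temperature −2.764,
  precipitation +1.653, UV-B +2.831, the published coefficient pattern)
  plus a λ = 0.6 phylogenetic residual (sd 2), thresholded at its empirical
  quantile so exactly 86 of 177 species are patterned.
- **UVP**: patterned species follow a linear model on centered raw
  predictors (intercept 0.45, altitude +2.85e-4 per m, temperature
  −2.70e-4 per °C) mapped into (0, 0.95) through a logit transform with a
  λ = 0.2 residual of sd 0.5 on the logit scale; uniform species draw from
  Uniform(0.95, 1). The mixture reproduces the bimodal UVP histogram and
  guarantees UVP ∈ [0, 1].
- **Flower color**: assigned within pattern class to hit the published
  crosstab (140/30/7 yellow/white/red; 94% of patterned species yellow;
  58%/7%/43% of yellow/white/red species patterned).

What the generator does *not* emulate: measurement error in UVP scoring,
non-Yule tree shape (birth–death imbalance, extinction), spatial
autocorrelation of the bioclimatic layers beyond the pairwise correlation
targets, and any pollinator-driven covariance. Selection of the patterned
subset also distorts subset-level predictor correlations relative to their
all-species targets (range restriction through the temperature-dependent
state). Passing tests therefore demonstrate internal correctness and
estimator calibration under the stated generative model, not fidelity to
any particular empirical dataset.

## Numerical choices

- Singular covariance matrices (zero-length terminal branches) get a ridge
  jitter of 1e-10 on the diagonal, with a warning.
- Multifurcations are handled natively in covariance computations; for
  contrasts they are resolved arbitrarily to zero-length branches
  (+1e-10), with a warning.
- λ optimization: golden-section with 10 restarts, tolerance 1e-8; both
  bounds evaluated explicitly so boundary optima are never missed.
- OU profile: log-spaced grid then bounded refinement; an `alpha_at_bound`
  flag marks boundary solutions.
- GEE: μ clamped to [1e-10, 1 − 1e-10]; Newton step-halving on the squared
  score norm; 20 deterministic perturbed BFGS restarts (RNG state saved and
  restored) if the first basin is a non-root minimum.
- Tie-break at the classification boundary: UVP = 0.95 is *uniform* (the
  rule is strictly-below for patterned).
- All generators require an explicit seed and are pure functions of
  (arguments, seed); the pipeline derives per-tree seeds as seed + index.

## Problem sizes in the tests and acceptance script

The suite calibrates estimators at sizes chosen to make Monte-Carlo noise
small relative to the asserted bands: K under BM (100 tips, 200
replicates), λ recovery (200 tips, 100 replicates), type-I error of the K
randomization and λ LRT (50 tips, 500 replicates), PGLS slope recovery
(100 tips, 100 replicates), and GEE sign recovery over 50 full synthetic
studies. `scripts/acceptance.R` runs the complete two-stage pipeline at the
full study scale — 177 species across 200 perturbed trees — in about two
minutes on one CPU.

## Known limitations

- The λ likelihood treats binary states as Gaussian; a threshold-model or
  Mk-based signal measure is out of scope.
- The OU fit assumes an ultrametric tree and a fixed root; non-ultrametric
  OU covariances are rejected rather than approximated.
- dfP is a heuristic effective sample size; it enters only the t reference
  of GEE P-values and is the least-identified element of the stack — its
  formula is validated by closed-form cases, not by external replication.
- With a single phylogeny there is one GEE "cluster", so only model-based
  (not sandwich) uncertainty is available.
- Mean-P aggregation across trees has no formal error-rate guarantee; it is
  a reporting convention, kept for comparability.
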