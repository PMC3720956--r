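---
title: "Life-stage niche modelling with stageniche: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life-stage niche modelling with stageniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stageniche)
```

`stageniche` estimates the fine-scale ecological niche of two co-occurring
life stages (dispersing adults, sedentary larvae) from presence-absence
(PA) and abundance (AB) data collected at nested sampling scales, and asks
how much of each stage's distribution is explained by abiotic conditions,
by biotic interactions, and by their shared (confounded) component. This
vignette is the package's own account of the statistical machinery: what
is modelled, which knobs exist, what the synthetic data emulate, and where
the design was genuinely open.

## The modelling chain

For each data set — a life stage observed at one location and one sampling
unit (pitfall trap, 1×1 m, 50×50 cm or 25×25 cm quadrat) — and each
response:

1. **Error families.** PA responses are Bernoulli observations and are fit
   with a binomial GLM (logit link). Ungrouped binary data cannot exhibit
   estimable overdispersion, so the quasibinomial alternative only
   triggers for grouped responses whose Pearson dispersion exceeds a
   threshold (default 1.5; `choose_family()`). AB responses are counts
   with strong spatial aggregation, modelled as negative binomial (log
   link) with the clumping parameter *k* estimated by profile maximum
   likelihood (via `MASS::glm.nb`). When the estimated *k* exceeds 10 —
   a conventional near-equidispersion bound; the threshold is
   configurable — the simpler Poisson family is used instead. Both
   switch rules log their trigger value.

2. **Screening** (`screen_predictors()`). Univariate GLMs keep candidates
   with likelihood-ratio *p* < 0.1, ranked by explained deviance
   (D0 − D1)/D0. A greedy pass in rank order drops candidates with
   |Spearman ρ| ≥ 0.7 against an already-retained variable. Variables
   measured at several scales (the cover variables at 25 cm/50 cm/1 m,
   the structure counts at 3 m/6 m radii) compete: only the
   best-ranked scale of a group survives, regardless of correlation. The
   chain ends with sequential VIF dropping (largest first, threshold 10),
   where VIFⱼ = 1/(1 − R²ⱼ) comes from ordinary least-squares auxiliary
   regressions on the predictor design matrix — the standard definition,
   not the GLM-weighted one. Whether scale competition belongs before or
   after the correlation filter is not fixed by the procedure's usual
   description; it is applied *within* the filter here, which guarantees
   at most one scale per variable without ever preferring a worse-ranked
   scale. An `allow`/`block` argument stands in for expert predictor
   preselection, which is not automatable.

3. **Model selection** (`stepwise_aic()`). Minimal adequate models by
   bidirectional stepwise AIC, launched twice: backward-led from the full
   post-screening scope and forward-led from the intercept-only model.
   Each step takes the single addition or deletion with the largest AIC
   decrease; the lower-AIC endpoint of the two runs wins. Ties are broken
   by fewer parameters, then lexicographically by predictor names — the
   two-start protocol and tie-breaks are determinism choices, not part of
   the canonical procedure. Three MAMs are selected per response: ABIOT
   (abiotic candidates), BIOT (biotic candidates), and FULL. The FULL
   scope is the *union of the predictors retained in the two MAMs*,
   re-selected by stepwise — combining the sets without re-selection
   would be the main alternative reading; re-selection was chosen because
   it never reports a FULL model that stepwise would reject.

4. **Fit statistics.** Nagelkerke R² is computed from deviances,
   R² = [1 − exp(−(D0 − D1)/n)] / [1 − exp(−D0/n)], which equals the
   rescaled Cox–Snell form for likelihood families. Quasibinomial fits
   use the underlying binomial deviances (identical under IRLS), and
   their stepwise comparisons use QAIC = −2ℓ/ĉ + 2p with ĉ estimated
   once from the largest model in scope; such models are flagged, since
   mixing quasi-likelihood and AIC has no unique convention. Per-category
   contributions (cover, resistance, soil, structure) are joint
   percentages of null deviance obtained by refitting the ABIOT MAM
   without each category.

5. **Evaluation** (`internal_evaluate()`, `external_evaluate()`).
   Internal: 100 iterations of a random 50/50 split; the MAM's predictor
   set is refitted on each half (refitting, rather than freezing the
   calibration coefficients, is standard practice and is recorded in the
   result metadata) and the AUC (PA; Mann–Whitney with midrank ties) or
   Spearman ρ (AB) is computed on the *pooled* held-out predictions of
   the iteration. Pooling the two folds gives one value per iteration and
   avoids single-class-fold failures; splits whose training half is
   single-class are redrawn, unstratified, staying closest to a plain
   "random 50% split". External: calibrate in one location, score the
   other. Qualitative bands (AUC: fail < 0.60 ≤ poor < 0.70 ≤ fair
   < 0.80 ≤ good < 0.90 < excellent; ρ analogously at
   0.20/0.40/0.60/0.80) are implemented left-closed, because strict
   inequalities on both sides would leave boundary values unassigned.

6. **Transferability** (`stage_transfer()`, `asymmetric_transfer()`). A
   stage's ABIOT MAM predicts the *other* stage's responses at the shared
   sampling points; transfer fails below AUC 0.70 (PA) or ρ 0.40 (AB),
   boundaries passing. Asymmetric transferability is reported as the
   percentage decrease of the weaker direction relative to the stronger,
   AT = (T̄_backward − T̄_forward)/T̄_backward × 100, aggregating the PA
   and AB models of a direction; the percentage base (the stronger
   direction) is a package decision, flagged in outputs, consistent with
   the reference results it mirrors ("a decrease of 6% … from A to B").

7. **Hierarchical partitioning** (`partition_r2()`). With two predictor
   sets the partition is closed-form: pure-abiotic = R²(FULL) − R²(BIOT),
   pure-biotic = R²(FULL) − R²(ABIOT), joint = R²(ABIOT) + R²(BIOT) −
   R²(FULL); the three components sum to R²(FULL) exactly. Components are
   deliberately *not* clipped at zero — with 2-dp rounded inputs a
   component can be slightly negative, and clipping would silently break
   the additive identity; values below −0.01 raise a warning instead.

8. **Residual autocorrelation** (`moran_permutation_test()`). Moran's I
   with row-standardized inverse-distance weights by default (k-nearest
   neighbours as the alternative): the usual choice for irregular point
   surveys, which the source procedure leaves unspecified. Significance
   by 1000 value permutations; the test is two-sided on |I − E[I]| by
   default with a one-sided "clumped" option, since spatial clumping is
   the usual alternative of interest. Deviance residuals are tested by
   default (Pearson and response residuals are options). Holm's step-down
   correction is applied across all models of a run.

## The synthetic survey generator

No field data accompany the design this package implements, so
`simulate_survey()` is a first-class module, not a fixture. It emulates:

* **Design.** Two locations, 120 sampling points each, placed uniformly
  at random in a square extent (sides roughly matching 9 and 15 ha) and
  rejection-sampled to a minimum spacing of 5.5 m; habitat types assigned
  by proportional stratification (largest-remainder counts over the
  location's habitat mix, five types per location).
* **Covariates.** The full abiotic catalog — 14 percentage-cover
  variables at three scales, nine vegetation-resistance and ten soil
  variables at 1 m, eight structure variables at 3/6 m radii. Cover
  variables are logit-normal with habitat-specific means driven by three
  latent gradients (bare ground, herbaceous cover, shrub cover); the
  three scale versions of a variable share a per-point latent value so
  any two scales correlate at `cross_scale_rho` (default 0.8) on the
  latent scale. The 16 cells of the quadrat grid draw their own 25 cm
  values from the same latent; soil particle-size fractions are Dirichlet
  so they sum to 100%.
* **Responses.** Congeneric adult/larval abundances (negative binomial,
  abiotic-only), then target adult PA (Bernoulli) and AB (negative
  binomial) with a congeneric biotic term, then larval point totals
  (negative binomial, with adult presence as a biotic term). Each point's
  larval total is spread over its 16 cells by a multinomial draw with
  log-linear cell weights on the cell-level bare-soil values — this keeps
  the scale conservation *exact* (cell sums are the 1 m abundance, the
  central 2×2 block the 50 cm abundance) and induces within-point
  crowding correlations without an explicit point process. Neighbour
  larval counts use the 12-cell ring around the central block (50 cm
  focal) and the clipped 8-neighbourhood (3/5/8 cells) of single cells.
* **Fine-scale selection.** Points enter the 25 cm data sets if their
  mapped larval total reaches the location threshold (5 and 3), ranked by
  descending total with ties broken by ascending point id, capped at 10
  and 11 points — threshold first, then rank, then cap; the ordering of
  these three rules is a package decision, made deterministic.

Default generating coefficients were set once so that the synthetic
occurrence statistics resemble the reference survey's reported figures
(adults in roughly a third of traps, larvae in ~45% of points, more
larvae in the first location, a few hundred individuals per location),
which also makes the fine-scale caps reliably fillable. Defaults live in
`synthetic_truth()` and are fully overridable.

What the generator does **not** emulate: spatial clustering of habitat
types (habitat labels are assigned independently of position, so
residual spatial autocorrelation is absent by construction — which is
what makes the generator usable for Moran type-I calibration); temporal
structure (instar progression, burrow closure, capture histories);
detection error; and any mechanistic coupling between adult PA and AB,
which are drawn as separate observation processes (trap presence vs
marked-individual counts), so a synthetic point can be "present" with
zero abundance. Consequently, passing tests demonstrate that the
*machinery* recovers known GLM structure under the stated design — not
that real surveys satisfy these assumptions.

## Numerical choices and degenerate inputs

* Linear predictors are clipped to ±30 before inverse-link during
  simulation (message emitted), preventing overflow.
* Perfect separation in a PA fit is detected (fitted probabilities
  within 1e−8 of 0/1) and returned as a flagged, iteration-capped fit
  rather than an error, so screening and cross-validation survive
  separable folds.
* Exact collinearity in the VIF cascade yields an infinite VIF and is
  dropped first; constant columns are dropped in the correlation filter
  with their own reason code.
* Non-convergent univariate or stepwise-candidate fits are excluded (or
  scored as +Inf criterion), never fatal; the final refit of a selected
  model must converge.
* Permutation p-values use the (1 + extreme)/(n_perm + 1) estimator, so
  p > 0 always; coincident points get a distance floor (1e−6 m) in the
  weight matrix.
* All stochastic stages are seeded; `run_full_analysis()` derives every
  stage seed from the single master seed, making reports bit-identical
  across reruns.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script simulations are sized to give stable
Monte-Carlo estimates while remaining quick on a single CPU: coefficient
recovery at n = 2000 over 100 replicates; stepwise-vs-exhaustive
agreement over 200 random 5-predictor instances (n = 150);
Moran type-I calibration over 500 null data sets of n = 100 with 199
permutations (the package default for real analyses remains 1000);
chance-level cross-validation at n = 200 with 100 iterations. These sizes
are the package's own choices for its validation experiments.

## Known limitations

* The partition applies to exactly two predictor sets; commonality
  analysis over more sets is out of scope.
* No GLMMs (a random quadrat effect at the finest scale is the natural
  extension, but added complexity without predictive gain in the
  reference analysis), no zero-inflated families, no spatially explicit
  correction of autocorrelated residuals.
* Quasibinomial model comparison (QAIC) has no unique convention; treat
  flagged quasi-model AICs as heuristic.
* AUC-based evaluation assumes true absences, which the trap/map survey
  design provides; the bands are conventions, not tests.
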