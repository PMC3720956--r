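# stageniche

Fine-scale ecological niche modelling for co-occurring life stages.

Species with complex life cycles occupy different niches at different life
stages: adults disperse and respond to habitat structure over metres, while
sedentary larvae are tied to the few centimetres around their burrow.
`stageniche` implements, as a tested and reusable pipeline, the analysis
chain used in fine-resolution, life-stage-resolved niche studies of ground
beetles and similar organisms: presence-absence and abundance GLMs for each
life stage at nested sampling scales, calibrated separately with abiotic
(scenopoetic) and biotic (Eltonian) predictor sets, evaluated by
cross-validation and cross-location transfer, and compared by hierarchical
partitioning of their explanatory power.

Because surveys of this kind are rarely deposited, the package ships a
seeded synthetic survey generator that emulates the study design the
pipeline assumes — two locations with 120 stratified-random sampling points
each (minimum 5.5 m spacing), a 4x4 grid of 25x25 cm cells nested in the
1x1 m quadrat at every point, a multiscale abiotic covariate catalog, and
GLM-structured responses with known coefficients — so every stage of the
pipeline can be validated against ground truth.

## The statistical core

For each data set (life stage x location x sampling scale) and response
(presence-absence `PA`, abundance `AB`):

* **Families.** `PA` is modelled with a binomial GLM (logit link;
  quasibinomial if grouped data are overdispersed); `AB` with a negative
  binomial GLM (log link, clumping parameter *k* estimated by maximum
  likelihood), switching to Poisson when *k* is large (weak aggregation).
* **Screening.** Candidate predictors are kept if their univariate GLM has
  *p* < 0.1 (likelihood-ratio test), ranked by explained deviance
  (D0 − D1)/D0; a greedy Spearman filter removes variables with
  |ρ| ≥ 0.7 against better-ranked survivors and keeps only the best scale
  of each multiscale variable; predictors are then dropped
  highest-VIF-first until all VIF = 1/(1 − R²ⱼ) < 10.
* **Selection.** Minimal adequate models (MAMs) by bidirectional stepwise
  AIC from both endpoints (full scope and intercept-only), taking the
  lower-AIC endpoint. Three MAMs per response: abiotic-only (`ABIOT`),
  biotic-only (`BIOT`), and `FULL` (stepwise over the union of the two
  MAMs' predictors).
* **Fit and contribution.** Nagelkerke
  R² = [1 − exp(−(D0 − D1)/n)] / [1 − exp(−D0/n)]; per-category explained
  deviance by refitting the ABIOT MAM without each category. Hierarchical
  partitioning over the two predictor sets:
  pure-abiotic = R²(FULL) − R²(BIOT), pure-biotic = R²(FULL) − R²(ABIOT),
  joint = R²(ABIOT) + R²(BIOT) − R²(FULL).
* **Evaluation.** Internal: 100 iterations of random 2-fold
  cross-validation, metric on pooled held-out predictions (AUC for `PA`,
  Spearman ρ for `AB`), with the usual qualitative bands (e.g. AUC > 0.9
  "excellent"). External: calibrate in one location, evaluate in the
  other. Transferability: one stage's ABIOT MAM predicting the other
  stage's occurrence, failing below AUC 0.70 / ρ 0.40; asymmetric
  transferability as the percentage decrease of the weaker direction.
* **Residual autocorrelation.** Moran's I on model residuals
  (row-standardized inverse-distance weights), permutation p-values, Holm
  correction across all models of a run.

## Worked example

```r
library(stageniche)

sv <- simulate_survey(seed = 1)      # two locations x 120 points
ds <- assemble_datasets(sv)          # the eight analysis data sets

trip <- fit_model_triplet(ds$ds1, "PA")   # adult PA, location A
trip
#> Model triplet (data set 1, PA, binomial)
#>   R2: ABIOT 0.50 | BIOT 0.30 | FULL 0.50
trip$abiot
#> Niche GLM (binomial), PA ~ BARESOIL_1 + HERB_1 + OPEN_3 + SHRUB_1 + SOIL_1
#>   n = 120 ; deviance 93.92 / 146.61 (null); AIC 105.92

internal_evaluate(ds$ds1, "PA", trip$abiot$predictors, trip$family,
                  n_iter = 100, seed = 2)
#> IE evaluation: AUC = 0.823 (good)

stage_transfer(trip$abiot, ds$ds5, "PA")   # adult model -> larvae (50 cm)
#> Transferability: AUC = 0.835 -> pass
```

The adult abiotic MAM recovers the generating signal (a positive bare-soil
and negative herb-cover effect), halves the null deviance (R² 0.50),
cross-validates as "good" (AUC 0.82), and transfers to the co-occurring
larval stage above the 0.70 failure threshold — the synthetic stages share
their abiotic niche by construction.

Partitioning a published table of (ABIOT, BIOT, FULL) R² triplets shipped
with the package:

```r
r2 <- read_r2_table(system.file("extdata", "table3_r2.csv",
                                package = "stageniche"))
summarize_partitions(partition_table(r2), "all")
#>   group    component     mean         sd  n
#> 1   all pure_abiotic 0.367500 0.22089213 16
#> 2   all  pure_biotic 0.020000 0.02366432 16
#> 3   all        joint 0.340625 0.23552689 16
```

The biotic sets add almost nothing beyond what the abiotic sets already
explain (pure-biotic 0.02): most of the biotic signal is contained in the
abiotic signature.

An end-to-end run over all eight data sets is
`run_full_analysis(run_config(seed = 1))`; `write_report()` serializes the
R²/AIC tables, coefficient and category-deviance tables, evaluation,
transfer, partition and Moran reports.

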