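---
title: "Linking the aging microbiome of huangjiu to its metabolic profile: methods"
author: "huangjiuML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking the aging microbiome of huangjiu to its metabolic profile: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Huangjiu (Chinese rice wine) matures for years in sealed pottery jars. During
that time its flavor chemistry — organic acids, esters, aldehydes, alcohols,
amino acids — keeps transforming, and the bacterial community living in the
wine lees (the sediment) may take part in those transformations. The package
quantifies how much of each metabolite's variation across a cohort of aged
samples is explainable from (i) physiochemical indexes (total acid, amino
nitrogen, reducing sugar, pH, conductivity) plus aging year, and (ii) the
aging microbiome profiled at species or genus level — and attributes the
predictions to individual features.

The cohort the design targets is 110 samples spanning aging years
3, 8, 10, 20 and 25. Because no public deposit of such a cohort exists, the
package ships a synthetic-data generator with planted, machine-readable
ground truth; every claim the test suite makes is a claim about recovery of
planted structure, not about any real cohort.

## Pipeline and model

1. **Metabolite preprocessing.** Metabolites with fewer than 50 non-missing
   measurements are dropped. Missing values (assumed left-censored at the
   detection limit) are imputed as the per-metabolite minimum of the observed
   values; levels are log10-transformed and z-scored. The z-score uses the
   sample standard deviation (n−1); this makes the worked example
   {10, 100, 1000} → {−1, 0, +1} unambiguous. An optional switch residualizes
   metabolites on storage time before modeling; it is off by default because
   aging year is itself a predictor of interest and removing it upstream
   would make the AFS/AMS comparison circular.
2. **Taxa preprocessing.** Taxa with mean relative abundance strictly above
   0.1% and strictly more than 10 nonzero measurements are kept (both read
   as strict inequalities). Retained rows are centered-log-ratio transformed,
   `clr_i = ln x_i − mean_j ln x_j`, with zeros replaced by 1e-10. The CLR is
   computed over the retained taxa only; because the transform is
   scale-invariant, not renormalizing after filtering changes nothing.
   Alpha diversity (Chao1, Shannon, Simpson) is computed from the count
   tables: Shannon in log base 2 (bits) and Chao1 in the bias-corrected
   small-sample form `S_obs + F1(F1−1)/(2(F2+1))` — both matching the
   defaults of the standard amplicon toolchain — with the log base and the
   classical Chao1 form available as switches.
3. **Feature groups.** PI = the five indexes plus aging year (the design
   treats aging year as part of the physiochemical description of a sample:
   PI is the model of everything measurable without sequencing); AMS/AMG = CLR abundances plus the three diversity indices at
   species/genus level; AFS/AFG = the same plus aging year; FM = the union,
   with aging year once and the diversity indices kept at both annotation
   levels under level-tagged names. Constant columns are dropped with a
   message (genus-level Chao1 is constant whenever sequencing depth saturates
   genus richness).
4. **Modeling.** Each metabolite is predicted by 5-fold cross-validation.
   Inside each training fold an optional random hyperparameter search (10
   draws, scored by inner 3-fold cross-validated explained variance) selects
   the configuration; the model refits on the full training fold and
   predicts the held-out fold. Scores are computed on the pooled out-of-fold
   predictions: explained variance `EV = 1 − Var(y − ŷ)/Var(y)` (sample
   variance) and `R² = 1 − Σ(y − ŷ)²/Σ(y − ȳ)²`. Learners: lasso (glmnet;
   search over regularization strength, log-uniform on [1e-4, 10]), random
   forest (ranger; fixed at 100 trees, depth 5, 5 samples per leaf, 2 to
   split, mtry 10 capped at the column count — the printed split criterion
   "Gini" is undefined for regression and is read as a typo for variance
   splitting), and gradient boosting (xgboost; search over learning rate,
   depth, minimum child weight, subsampling). Each model is run repeatedly
   (default 10 runs) with fold assignments seeded per (metabolite, run).
5. **Significance.** Each bootstrap iteration redraws the 5-fold partition,
   resamples every training fold with replacement to its original size
   (held-out folds are never resampled), retrains at fixed parameters, and
   records the pooled out-of-fold EV. The 95% CI is the 2.5/97.5 percentile
   over B = 100 iterations; since no p-value construction is prescribed for
   this scheme anywhere standard, the package defines "significantly
   explained" by the one-sided empirical p-value against the EV ≤ 0 null
   with add-one smoothing, `p = (1 + #{EV_b ≤ 0})/(B + 1)`. No
   multiple-testing correction is applied by default; a Benjamini–Hochberg
   helper is provided.
6. **Attribution.** SHAP values of the tree-ensemble fold models are computed
   with the package's own TreeSHAP (the polynomial-time tree-path algorithm
   with the path-dependent, cover-weighted conditional-expectation value
   function), implemented in C++ over trees extracted from ranger and
   xgboost. SHAP is computed on held-out folds only, so attribution reflects
   generalizable structure; a train-set switch exists for diagnostics. The
   per-(metabolite, feature) summary is the mean absolute SHAP over pooled
   held-out samples, averaged over runs, multiplied by the sign of the
   Spearman correlation between the raw feature and the metabolite over all
   samples ("directional mean absolute SHAP"). Because metabolites and CLR
   features are standardized, these values are comparable across
   metabolites. Linear-model attribution is out of scope.
7. **Reporting.** Spearman association matrices (average-rank ties, two-sided
   p from the t approximation on pairwise-complete counts), a two-way
   hierarchical cluster map of well-predicted metabolites (EV > 0.3;
   Euclidean distance on z-scores, average linkage, cut into 3 metabolite and
   3 sample clusters by default), and one-way ANOVA of an index across sample
   clusters.

## The synthetic generator

`generate_dataset()` draws, per seed: aging years allocated proportionally to
the configured weights; physiochemical indexes with mild aging-year trends
and the expected negative total-acid/pH coupling (only rank structure matters
downstream); a species table from log-normal latent abundances renormalized
to the simplex, with the dominant species' fraction controlled on the logit
scale around 59%, one species monotone in aging year (in expectation), one in
total acid, and one fading with age; zeros created by a detection floor
(1e-4) with renormalization; counts by multinomial sampling at 10,000
reads/sample so count-based diversity is meaningful; genus tables by
aggregation through a species→genus map. Metabolites are sums of planted
effects on standardized sources — linear `x`, saturating `x/(1+|x|)`,
threshold `1(x > median)`, or interaction `x1·x2` — plus Gaussian noise on
the log scale (sd 0.5 by default), exponentiated to concentrations, and
left-censored below the per-metabolite 10% quantile (exactly
`floor(q·n)` smallest values, ties broken by row index). Three "rare"
metabolites are censored at 60% so the measurement filter has real work to
do. Species named in the effect table get a floor on their baseline log
abundance: an effect planted on a taxon below the detection filter would be
unrecoverable by construction, which would test the filter, not the model.

Ground truth records each effect's sign; interactions get `NA` because their
marginal monotone direction is undefined. For monotone forms the planted
sign equals the sign of the population Spearman correlation between source
and target in the noiseless limit.

What the generator does **not** emulate: sequencing reads and ASV inference
(it starts from an annotated table), chemistry-level measurement structure
(chromatograms, batch effects), phylogenetic correlation among taxa, and any
real missingness mechanism — left-censoring is an assumption. Passing tests
therefore demonstrate correct recovery of planted statistical structure
under compositional, sparse, noisy data of the study's shape; they do not
certify performance on a real cohort.

## Numerical choices and caveats

* **Seeds.** One global seed fans out to per-stage/per-unit child seeds by a
  fixed integer hash kept below 2^31, so stages are independently
  reproducible and the full pipeline is byte-deterministic.
* **Compositional closure.** A metabolite planted on a single taxon is not an
  exact function of that taxon's CLR feature (the CLR removes the per-sample
  row mean), so even noiseless taxon-driven metabolites cap below EV = 1.
  The noiseless-recovery checks therefore use drivers that appear verbatim
  as features (aging year, the indexes); taxon drivers are validated through
  sign recovery and ablation instead.
* **Random-forest approximation.** With the fixed parameters (mtry 10 among
  ~80 full-model features, depth 5), the forest dilutes single strong
  signals; gradient boosting or the lasso recover noiseless linear signal to
  EV ≥ 0.95, the forest typically to 0.4–0.85. This mirrors the usual
  bias of fixed-mtry forests in wide feature spaces and is why the
  learner-comparison stage exists.
* **Held-out SHAP noise.** Attribution on held-out folds at n = 110 leaves
  irrelevant features with small nonzero mean |SHAP| (~0.01–0.03), an order
  of magnitude below planted drivers; exact zeros are only seen in-sample on
  noiseless fits.
* **float32.** xgboost stores thresholds and leaf values in single
  precision; the extracted double-precision ensemble agrees with xgboost's
  own predictions to ~1e-6 and split decisions are made in float32 to match
  it exactly. ranger trees are double-precision and agreement is exact.
* **Ties and degeneracies.** Censoring ties break by row index; cluster
  labels are canonicalized by first appearance over name-sorted columns, so
  results are invariant to input order; a zero within-cluster variance ANOVA
  reports F = Inf, p = 0; constant features get Spearman sign 0 with a
  warning; a constant metabolite is an error at standardization.

## Problem sizes used by the tests

The suite exercises the full study geometry (110 samples) where the claim
depends on it — noiseless recovery, the 200-metabolite null suite at B = 50
bootstrap iterations, sign recovery over the 34 monotone planted effects,
the 10-seed ablation, and the 10-run learner comparison — and reduced
cohorts (40 samples, 12 taxa, 6 metabolites) for interface and determinism
checks. These sizes are the package's chosen testing design: large enough
for each property to be statistically meaningful, small enough to run
routinely.

## Known limitations

* Correlational throughout: attributions are predictive associations, not
  causal effects.
* The bootstrap p-value definition is the package's own convention;
  alternatives such as permutation nulls are a documented possible
  extension.
* Only one gradient-boosting backend (xgboost) is provided.
* No rarefaction, beta diversity, or phylogenetic diversity; no interaction
  SHAP values.
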