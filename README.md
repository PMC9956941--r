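# huangjiuML

Machine-learning analysis of how the aging microbiome and physiochemistry of
naturally aged huangjiu (Chinese rice wine, matured for years in sealed
pottery jars) shape its metabolic profile.

During jar aging, flavor metabolites — organic acids, esters, aldehydes,
alcohols, amino acids — keep transforming, and bacteria in the wine lees may
drive part of that chemistry. The package answers two questions for a cohort
of aged samples profiled with paired metabolomics, physiochemistry and 16S
taxa tables:

1. **How much of each metabolite is predictable**, and from what? Each
   metabolite is predicted by cross-validated learners from six named
   feature groups: `PI` (total acid, amino nitrogen, reducing sugar, pH,
   conductivity, aging year), `AMS`/`AMG` (CLR-transformed species/genus
   abundances + Chao1/Shannon/Simpson diversity), `AFS`/`AFG` (the same plus
   aging year) and `FM` (everything). Scores are out-of-fold explained
   variance `EV = 1 − Var(y−ŷ)/Var(y)` and `R² = 1 − Σ(y−ŷ)²/Σ(y−ȳ)²`,
   with significance from a bootstrap that resamples training folds
   (`p = (1 + #{EV_b ≤ 0})/(B+1)`).
2. **Which features drive the predictions?** Shapley values of the
   tree-ensemble fold models, computed on held-out folds by the package's
   own C++ TreeSHAP (path-dependent value function, exact for ranger trees,
   float32-faithful for xgboost), summarized as *directional mean absolute
   SHAP*: mean |SHAP| per feature × the sign of the feature–metabolite
   Spearman correlation.

Because the target cohort (110 samples, aging years 3–25) has no public
deposit, the package ships a synthetic-data generator with planted,
machine-readable ground truth — compositional sparse taxa tables with a
dominant taxon near 59% mean abundance, age- and acid-correlated taxa, and
metabolites driven by aging year, taxa, indexes, nonlinearities or nothing —
so every pipeline stage is tested end to end against known truth. See
`vignettes/methods.Rmd` for the full model description and design choices.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script prints what it found and writes tables under `results/`.

```sh
Rscript analysis/01_simulate.R        # cohort + ground truth -> results/data
Rscript analysis/02_preprocess.R      # QC, CLR, diversity    -> results/prep
Rscript analysis/03_compare_learners.R
Rscript analysis/04_feature_groups.R
Rscript analysis/05_significance.R
Rscript analysis/06_attribution.R
Rscript analysis/07_report.R
```

Output of the run checked into this repository's development log:

```
samples:             110
dominant taxon mean: 0.586
metabolites:         80 ( 1045 censored values )

metabolites kept: 77 — dropped: m078, m079, m080
species kept: 48 of 60

metabolites with R^2 > 0.3 (mean ± sd over runs):
  lasso          26.3 ± 0.6
  random_forest  26.7 ± 0.6

adding aging year (AMS -> AFS) improved 64 % of metabolites

23 of 77 metabolites significantly explained by the physiochemical indexes
median EV among significant metabolites: 0.736
significant among pure-noise metabolites: 0 of 41

metabolites with at least one strong predictor (mean |SHAP| > 0.1): 34 of 77
planted signs recovered (drivers present in AFS): 28 of 34

well-predicted metabolites (EV > 0.3): 22
total acid across sample clusters: F = 86.42 , p = 4.6e-23
```

Reading: the three heavily censored metabolites fall to the 50-measurement
filter; the random forest matches the lasso on linear signal and adds the
planted nonlinear metabolites; the bootstrap flags no pure-noise metabolite;
directional SHAP recovers the planted effect signs for every driver that is
present in the AFS feature space (the 6 index-driven effects have no AFS
feature to attribute to); and the sample clusters of well-predicted
metabolites differ sharply in total acid, the index that tracks huangjiu
quality.

The same pipeline runs on real data from TSV tables (see
`read_study_tables()`, or `read_taxa_biom()` for BIOM input) through
`run_pipeline(pipeline_config(input_dir = ...))`.

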