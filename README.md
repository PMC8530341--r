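# kneemorph

Quantitative knee-osteoarthritis (KOA) biomarkers from multi-structure knee
segmentations, in R.

Given labeled 3-D segmentations of six knee structures — femoral bone (FB),
tibial bone (TB), femoral cartilage (FC), medial/lateral tibial cartilage
(mTC/lTC) and both menisci (mM/lM) — the package computes two families of
candidate imaging biomarkers and evaluates them against clinical endpoints:

* **MEAS** — 14 direct measurements: height-normalized volumes
  $V_i / h$ (mm³/m) for FC, TC, mTC, lTC, mM, lM; meniscal surface areas
  $A_i$ (mm²); area-to-volume ratios $R_{A,V} = A_i / V_i$ (1/mm);
  medio-lateral meniscal extrusions $E_i$ (mm); and tibial coverages
  $TC_i$ (%).
* **LDSE** — a low-dimensional shape encoding: per structure, a statistical
  shape model (generalized Procrustes alignment, then tangent-space PCA
  about the mean shape) is fitted on the cohort; each knee is encoded by
  its leading mode coefficients, and a combined encoding concatenates the
  first 75 coefficients of FB, TB, mM and lM (300 features).

Feature sets are evaluated for ordinal grade classification
(Kellgren-Lawrence grade, medial/lateral joint space narrowing) and event
prediction (incident KOA, total knee replacement within 1-5 years) with
balanced Monte-Carlo cross-validation of linear SVMs: per repeat, classes
are subsampled to the minority size, split 90/10, min-max normalized on the
training split, fitted and scored. Reported metrics are balanced accuracy
$BA = \tfrac{1}{k}\sum_c \mathrm{recall}_c$, weighted kappa
$\kappa_w = 1 - \sum w_{ij} O_{ij} / \sum w_{ij} E_{ij}$ with
$w_{ij} = |i-j|/(k-1)$, and the Mann-Whitney ROC AUC from the SVM decision
margins, each as mean ± SD over repeats. Feature importance for TKR uses
logistic regression with per-SD odds ratios and Wald 95% intervals.

Real cohorts of this kind are access-restricted, so the package includes a
first-class **synthetic knee generator**: template meshes for all six
structures, smooth random shape modes, and severity-coupled deformations
(cartilage thinning, volume-preserving meniscal flattening, meniscal
extrusion, marginal bone bumps) driven by a latent severity that also
generates the ordinal grades and event outcomes. Every measurement the
pipeline makes can therefore be checked against a planted ground truth.

## Worked example

```r
library(kneemorph)

cfg <- cohort_config(n_knees = 300, seed = 11)
cohort <- sample_cohort(cfg)                 # records + per-knee meshes
ft <- build_feature_table(cohort)            # 14 MEAS + LDSE blocks

scfg <- split_config(n_repeats = 50, seed = 99)
run_task(ft, cohort$records,
         task_spec("classification", "klg", list(0, 4),
                   feature_set = "LDSE-COMB + MEAS"), scfg)
#> KLG 0 vs 4 | LDSE-COMB + MEAS: BA 1.00 +/- 0.00, kappa 1.00 +/- 0.00, AUC 1.00 +/- 0.00 (n=103, 50 repeats)

run_task(ft, cohort$records,
         task_spec("classification", "klg", list(0, 2),
                   feature_set = "LDSE-COMB + MEAS"), scfg)
#> KLG 0 vs 2 | LDSE-COMB + MEAS: BA 0.91 +/- 0.10, kappa 0.81 +/- 0.20, AUC 0.98 +/- 0.04 (n=115, 50 repeats)

run_task(ft, cohort$records,
         task_spec("prediction", "tkr", horizon_years = 1,
                   feature_set = "MEAS"), scfg)
#> tkr within 1 yr | MEAS: BA 0.74 +/- 0.12, kappa 0.47 +/- 0.24, AUC 0.80 +/- 0.14 (n=300, 50 repeats)
```

Separating healthy knees (KLG 0) from severe disease (KLG 4) is essentially
solved on this cohort; early disease (KLG 0 vs 2) is markedly harder; and
the morphometric measurements alone already predict the synthetic TKR
endpoint well above chance. The same orderings the harness is designed to
expose — wide grade gaps easier than narrow ones, combined multi-structure
encodings at least as good as any single structure, severity-coupled
feature sets out-predicting decoupled ones — are asserted by the test
suite.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/kneemorph.R simulate --config cohort.yaml --out cohort/
Rscript inst/cli/kneemorph.R features --masks cohort/masks \
        --meta cohort/records.csv --out features.csv
Rscript inst/cli/kneemorph.R pipeline --config pipeline.yaml --out results/
```

All outputs are byte-reproducible for a fixed configuration and seed.

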