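# necrostrat

Prognostic stratification of lung adenocarcinoma (LUAD) by
necroptosis-related lncRNAs, from two directions at once:

* **Bulk arm** — screen differentially expressed lncRNAs correlated with
  necroptosis genes, evaluate the published four-lncRNA **NecroLRS** risk
  score, split patients at a Youden-index cutoff, and quantify the split
  with Kaplan–Meier curves, the log-rank test, and time-dependent ROC AUC.
* **Single-cell arm** — apply cell-level quality filters and a per-sample
  doublet-rate calibration, then run an iterative module-score + K-means
  classifier that first separates malignant from non-malignant epithelial
  cells and then, nested within the malignant compartment, calls
  NecroLRS-High and NecroLRS-Low cell subsets. Per-sample subset ratios
  link the single-cell calls back to immune-cell composition.

Both arms are exercisable end to end on synthetic cohorts with planted
ground truth (negative-binomial single-cell counts with nested planted
subpopulations; exponential proportional-hazards survival cohorts), so
every stage is testable against known answers.

## The model

The risk score of a sample is a fixed linear model over four lncRNAs on the
log-expression scale:

```
NecroLRS = 0.2486147 · log2(TPM_FAM83A-AS1 + 1)
         + 0.1862710 · log2(TPM_LINC02323 + 1)
         + 0.3906980 · log2(TPM_OGFRP1   + 1)
         + 0.6592927 · log2(TPM_WWC2-AS2 + 1)
```

Patients are called NecroLRS-High when their score strictly exceeds the
cohort's Youden-index cutoff (the threshold maximizing
J = sensitivity + specificity − 1 against vital status).

In the single-cell arm, each cell receives a "positive" score Sm and a
"negative" score Sn: the mean log-normalized expression of a signature
minus the mean of 100 expression-matched control genes per signature gene,
drawn from 25 bins of average expression. K-means (k = 2) on the (Sm, Sn)
plane splits the cells; the positive centroid is the cluster with higher
mean Sm and lower mean Sn; differential expression between the two called
groups refines both signatures, and the loop repeats until the marker sets
stabilize.

## Worked example

Score and stratify a synthetic 120-patient cohort with planted hazard
structure:

```r
library(necrostrat)
coh    <- generate_bulk_cohort(bulk_sim_config(n_samples = 120, seed = 42))
scores <- necrolrs_score(coh$expression)
round(head(scores, 4), 4)
#>  S0001  S0002  S0003  S0004
#> 2.1879 2.2278 3.2557 3.2076

yc    <- youden_cutoff(scores, coh$survival$event)
strat <- stratify(scores, yc$cutoff, provenance = "synthetic training")
table(strat$group)
#>  Low High
#>   50   70

lr <- km_logrank(coh$survival, strat$group)
c(chisq = lr$chisq, p = lr$pval)
#> log-rank chisq: 39.94, p = 2.62e-10

time_dependent_auc(scores, coh$survival, horizon = 365)
#> 1-year AUC: 0.787
```

The score of sample S0001 (2.19) is the weighted sum above evaluated on its
four lncRNA TPM values; the Youden cutoff 2.77 splits the cohort into 70
High and 50 Low patients, whose survival separates decisively (log-rank
p ≈ 3 × 10⁻¹⁰) because the generator plants a real hazard gradient along
the signature genes.

For the single-cell arm, `run_pipeline(pipeline_config(seed = 1))` chains
synthetic-data generation, QC, normalization, nested classification,
stratification, evaluation, and subset statistics, writing per-cell labels,
risk groups, and a JSON report under one run directory.

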