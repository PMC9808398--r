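---
title: "Methods: necroptosis-lncRNA risk scoring and nested cell-state calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: necroptosis-lncRNA risk scoring and nested cell-state calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(necrostrat)
```

# Scope

`necrostrat` implements a two-arm prognostic workflow for lung
adenocarcinoma transcriptomics. The bulk arm screens necroptosis-correlated
lncRNAs and evaluates a fixed four-lncRNA linear risk score (NecroLRS) with
Youden-cutoff survival stratification. The single-cell arm runs an
iterative module-score + K-means classifier that calls malignant cells
within the epithelial compartment and, nested inside the malignant calls,
NecroLRS-High and NecroLRS-Low subsets. Model *fitting* (LASSO, stepwise
Cox), consensus clustering, immune deconvolution, enrichment analysis,
trajectory and cell-communication analysis are deliberately out of scope:
the score is used as published, and everything around it is screening,
stratification, and evaluation machinery.

# The bulk arm

## Expression units

TPM is the working unit. `fpkm_to_tpm()` renormalizes each sample to a
constant total of $10^6$:
$\mathrm{TPM}_g = \mathrm{FPKM}_g / \sum_g \mathrm{FPKM}_g \times 10^6$.
The map is idempotent, so TPM input passes through unchanged. All
score-related transforms use $\log_2(\mathrm{TPM}+1)$.

## Screening

Candidate lncRNAs pass two strict gates, both exposed as parameters with
the published values as defaults:

* differential expression between tumor and normal: $|\log_2 FC| > 1$ and
  BH-adjusted $p < 0.05$;
* correlation with at least one necroptosis gene: $|r| > 0.4$ (Pearson)
  with $p < 0.001$.

Both inequalities are strict — a gene sitting exactly on a boundary is
excluded. The differential test is a per-gene two-sided Wilcoxon rank-sum
on $\log_2(\mathrm{CPM}+1)$; a distribution-free test keeps the contract
simple and makes the brute-force test oracle exact. Constant genes get
$p = 1$ rather than `NA` so downstream filters need no special cases.
`cox_screen()` then fits one univariate proportional-hazards model per
gene (partial likelihood, via the survival package); zero-variance genes
and non-converging fits are flagged and excluded rather than silently
dropped.

## The risk score and its cutoff

`necrolrs_model()` carries the published model: genes FAM83A-AS1,
LINC02323, OGFRP1, WWC2-AS2 with coefficients 0.2486147, 0.1862710,
0.3906980, 0.6592927 applied to $\log_2(\mathrm{TPM}+1)$. The score is
linear in each transformed input with slope equal to the coefficient — the
unit tests verify this by finite differences.

`youden_cutoff()` maximizes $J = \text{sensitivity} + \text{specificity}
- 1$ over the midpoints between adjacent sorted unique scores; ties in $J$
resolve to the smallest threshold, and a positive call is `score >
threshold`. The outcome variable for the cutoff is vital status (death by
end of follow-up). That choice was genuinely open — a time-horizon-specific
outcome would also be defensible — but vital status is the simplest reading
and the `provenance` field of `stratify()` lets users recompute the cutoff
per cohort, so the choice is recalibratable rather than baked in. Ties at
the cutoff go Low.

Evaluation uses the survival package's product-limit estimator and log-rank
test (checked in the tests against a hand hypergeometric
observed-minus-expected computation). The time-dependent AUC is a
cumulative-case / dynamic-control estimator with
inverse-probability-of-censoring weights from the reversed-event
Kaplan-Meier curve: cases ($T_i \le t$, $\delta_i = 1$) weigh
$1/\hat G(T_i^-)$, controls ($T_i > t$) weigh $1/\hat G(t)$, tied scores
count one half. With no censoring it reduces to the empirical AUC, which
gives the test suite its negation-symmetry check ($AUC \mapsto 1 - AUC$).

# The single-cell arm

## Quality control

Four strict per-cell rules, all parameters with their published defaults:
UMI count > 1000, 500 < detected genes < 6000, mitochondrial percentage
< 50, hemoglobin percentage < 1. Percentages are
$100 \times \text{flagged counts}/\text{total}$, defined 0 for an all-zero
cell. Boundary cells are removed — the filter is the conjunction of four
strict inequalities, and the tests enforce exactly that against a
brute-force per-rule mask.

The expected doublet rate of a sample is the linear calibration
$\text{rate} = \text{detected features} \times 8 \times 10^{-6}$, where
"detected features" is the number of genes with nonzero counts in the
sample. The raw product exceeds 1 above 125,000 features, so the value is
clipped to $[0, 1]$; the calibration source does not state a clip, but an
expected proportion above 1 is meaningless. Doublet *identification* is
delegated to external tools; `remove_expected_doublets()` only removes the
expected count of top-scoring cells given a caller-supplied score.

## Module scores with binned controls

For a gene signature $S$, the per-cell score is

$$\text{score}(c) = \frac{1}{|S|}\sum_{g \in S} x_{gc}
  - \frac{1}{|C|}\sum_{g \in C} x_{gc}$$

on the log-normalized matrix ($x = \log(1 + \text{count}/\text{total}
\times 10^4)$), where $C$ is a pooled control multiset: all genes are
ranked by mean expression and cut into 25 near-equal bins (ties broken by
input gene order — the binning constant is published, the tie rule is
ours), and each signature gene contributes 100 genes drawn uniformly
without replacement from its own bin, excluding itself; a bin smaller than
100 is taken whole. Controls are pooled rather than paired per signature
gene, and duplicates keep their multiplicity — these conventions are pinned
by an explicit-loop oracle in the tests (agreement to $10^{-10}$ on random
matrices). Scoring uses the normalized matrix for both binning and
subtraction; raw-versus-normalized is not stated by the scoring convention
we mirror, and normalized is the only choice under which the
shift-invariance property (adding a constant to the matrix leaves scores
unchanged) holds exactly.

## The iterative classifier

One round, given a positive/negative signature pair:

1. score every cell with both signatures (fresh control draws each round,
   from streams derived from the pipeline seed);
2. K-means with $k = 2$ on the (Sm, Sn) plane — 10 restarts, best
   within-cluster sum of squares, restart seeds derived from the pipeline
   seed;
3. identify the positive centroid: the cluster with higher mean Sm **and**
   lower mean Sn. The published rule covers only these two concordant
   branches; on discordant patterns (one cluster higher in both) the
   positive score dominates — higher mean Sm wins, then lower mean Sn, and
   exact ties on both axes are an error. The tie-break is our design
   choice, surfaced here and in the function documentation;
4. refine both signatures: per-gene two-sided Wilcoxon rank-sum between
   the called groups, BH adjustment, significance $\alpha = 0.05$, the top
   50 significant genes per direction ranked by absolute log fold change.

Convergence: both refined sets identical to the previous round's, or
Jaccard $\ge 0.99$ on both sides for two consecutive rounds; the published
description says only that markers "reach convergence", so the tolerance is
ours. A round finding no significant genes on a side leaves the signatures
unchanged and converges. A revisited signature state without stability is
flagged as oscillation and the round with the widest centroid separation is
returned — never a silent confident call. The iteration cap defaults to 20.

`nested_three_way()` applies the classifier twice: malignant versus
non-malignant on all epithelial cells, then NecroLRS-High versus -Low on
the malignant calls only (re-binning on the subset, since scoring and
binning must see the same cell population). Fewer than 10 malignant cells
skips round 2 with a flag. Initial signatures come from bulk differential
expression (`derive_initial_signatures()`: top 50 significant genes per
direction), intersected with the matrix's genes at scoring time.

## Per-sample subset statistics

$\text{Ratio}_i = n^{\text{High}}_i / (n^{\text{High}}_i +
n^{\text{Low}}_i)$ over the NecroLRS-classified malignant cells of sample
$i$; undefined (an error, not 0) when a sample has no classified cells.
Compartment proportions are computed within myeloid or T compartments and
ordered by ascending ratio. `proportion_correlation()` chooses Pearson
versus Spearman automatically: Shapiro-Wilk at $\alpha = 0.05$ on both
vectors, Pearson only when neither rejects. The published rule is
qualitative ("Gaussian" versus "abnormal"); the test and level are our
concretization, and the method actually used is always recorded in the
output. Samples with empty compartments are dropped from correlations with
a warning — undefined proportions must never silently become zeros.

# Synthetic data

The generators define the conditions under which the pipeline is tested;
they are first-class, tested code.

**Single cell.** Counts are negative binomial with variance
$\mu + \mu^2/\phi$ (dispersion $\phi = 2$), per-gene baseline means
log-normal (sdlog 1) around `nb_mean = 2` — chosen so a default cell's UMI
total (≈ 3000) and detected-gene count sit inside the standard QC gates,
making the default configuration self-consistent end to end. Four disjoint
marker sets of 50 genes are planted: up in malignant cells, up in
non-malignant cells, and — within the malignant compartment — up in the
High subset and up in the Low subset, each multiplied by
`marker_fold_change` (default 4) in its carrying population. Defaults plant
2000 cells, 1000 genes, 50% malignant, 40% High within malignant.
Fractional class sizes round to the nearest integer with at least one cell
per planted class. Mitochondrial (5%) and hemoglobin (1%) genes are flagged
in metadata and named with `MT-`/`HBB-` prefixes. The generator does *not*
emulate doublets, batch effects, ambient RNA, or realistic gene-length
structure — so passing recovery tests demonstrates the classifier's
correctness on clean nested structure, not robustness to those artifacts.

**Bulk.** Event times are exponential with subject hazard
$h_0 \exp(\beta^\top x - \overline{\beta^\top x})$, where $x$ is the
signature genes' $\log_2(\mathrm{TPM}+1)$ (normal, mean 2, sd 1, truncated
at 0) and $\beta$ defaults to $(1,1,1,1)$ on the four model lncRNAs —
unit planted log-hazards give an unambiguous recovery target while the
published coefficients remain the scoring model. The baseline hazard is
0.002/day (median survival around one year at the mean predictor).
Censoring is independent exponential with its rate solved numerically so
the expected censored fraction equals `censoring_rate` (default 0.3); an
all-censored draw is resampled with a warning, never returned. Defaults:
300 samples, 200 genes, non-signature genes pure log-normal noise.

# Numerical conventions and problem sizes

All randomness flows from one master seed through per-stage streams
(`derive_seed()`), so the full pipeline is bit-reproducible and the
iterative classifier's fresh control draws are deterministic. Reruns of
`run_pipeline()` with the same configuration produce identical label
tables.

The test suite exercises the classifier at the generator defaults (2000
cells, fold change 4, 20 seeds; adjusted Rand index against planted truth)
and over a fold-change ladder {1.5, 2, 4} with fixed seeds for the
monotonicity property; statistical calibration runs use 400 null genes for
the Cox type-I rate, 300 null lncRNAs at $n = 500$ for the correlation
screen, and 50 seeds of the default bulk cohort for the Youden-stratified
log-rank check. Smaller fixtures (400 cells, 300 genes) back the per-round
unit tests.

# Limitations

* The classifier assumes two genuinely separable states per round; on
  structureless data K-means still returns two clusters, and the guards
  (oscillation flag, non-convergence, near-zero recovery at fold change 1)
  are statistical, not certificates.
* The Youden cutoff against vital status ignores follow-up length; cohorts
  with very different censoring patterns should recalibrate per cohort, as
  the provenance field encourages.
* The time-dependent AUC estimator assumes censoring independent of both
  score and survival.
* Wilcoxon-based differential expression does not model counts; with very
  few cells per group, moderated-variance methods would be more powerful
  than the rank test used here.
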