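---
title: "Per-locus methylation prediction: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-locus methylation prediction: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pretimeth)
```

## The problem

Illumina's 450K beadchip interrogates roughly 450,000 CpG loci; its EPIC
successor roughly 850,000. Large public archives are dominated by 450K
profiles, so analyses that need EPIC-level coverage must predict the
missing loci. pretimeth builds **one independent regression model per
target CpG** rather than one general-purpose model: loci covered by EPIC
but not 450K are *model loci* (responses), loci covered by both chips
are *feature loci* (candidate predictors). A per-locus model comes with
its own cross-validated error, so a downstream analyst can keep only the
loci that are predicted accurately — the property that distinguishes
this approach from global imputation.

## Feature selection

For a model locus $i$ with cross-sample beta vector
$\beta_{CpG_i} = (\beta_i^1, \dots, \beta_i^n)$, three candidate
predictors are scored against every feature locus $j$:

* **Co-methylated locus** — the argmax of the Pearson correlation
  $\mathrm{PearsonMeth}_{ij} = \operatorname{cov}(\beta_{CpG_i},
  \beta_{CpG_j}) / (\sigma_{\beta_{CpG_i}} \sigma_{\beta_{CpG_j}})$
  across training samples. The search is genome-wide across
  chromosomes: co-methylation is frequently distal, and restricting the
  search to a fixed flank would forfeit exactly the loci that benefit
  most.
* **Nearest neighbouring locus** — the same-chromosome feature locus at
  minimal base-pair distance, optionally capped (the 2 kb cap is the
  conventional comparison point; loci with no candidate inside the cap
  have this feature absent).
* **Most similar flanking sequence** — each locus's ±200 bp window
  (the CpG dinucleotide plus 200 bp each side) is summarized by the
  occurrence frequencies of all 1- to 4-mers — $4 + 16 + 64 + 256 =
  340$ features, each $k$ block normalized by the count of valid
  $k$-length windows (windows containing `N` are skipped) — and the
  argmax of the Pearson correlation between these 340-vectors picks the
  match.

Correlations use pairwise-complete deletion with a floor of
`min_samples = 30` complete pairs (public cohorts carry missing probes;
below a few dozen pairs a correlation estimate is too unstable to rank
candidates). Argmax ties are broken by smallest genomic distance, then
smallest probe ID, so builds are reproducible. All features are defined
on training samples only.

## The per-locus regression model

The default model for locus $i$ in sample $k$ is a logistic curve on
the selected feature value $x^k$:

$$\hat\beta_i^k = \mathrm{sigmoid}(w_i x^k + b_i)
  = \frac{1}{1 + e^{-(w_i x^k + b_i)}}$$

Beta values are fractions in $[0,1]$, so the fit treats them as
fractional responses and minimizes the binomial deviance
$\sum_k -[\,\beta_i^k \log p_k + (1-\beta_i^k)\log(1-p_k)\,]$. This
reduces to ordinary logistic regression when responses are binary and
keeps the output interpretable as a methylation probability. The
objective is convex; it is solved by iteratively reweighted least
squares with a step-halving safeguard, tolerance $10^{-8}$ on the
maximum coefficient change, at most 100 iterations, and responses
clipped to $[10^{-6}, 1-10^{-6}]$ so the deviance stays finite at the
boundaries. An ordinary least squares alternative
$\hat\beta_i^k = \alpha_i x^k + c_i$ (predictions clipped to $[0,1]$)
is provided for comparison; on saturating, sigmoid-shaped
relationships the logistic family fits better, on shallow interior
trends the two are nearly equivalent.

Up to three features can enter the linear predictor (co-methylated,
then nearest-neighbour, then sequence-match), but every feature must be
observed for a sample to be predictable, so adding features can only
shrink the predictable set — the package defaults to the co-methylated
feature alone, which carries nearly all of the signal.

## Cross-validation, metrics and accuracy categories

Each locus is assessed by 5-fold cross-validation: samples with
complete response and features (at least `min_fit_samples = 30`) are
partitioned into five seeded folds, each fold is predicted by a model
fitted on the other four, and eight metrics are computed on the
**pooled** out-of-fold predictions — pooling yields the single RMSE per
locus that the categorization needs. The metrics are Pearson R, RMSE,
MAE, and — after binarizing at beta 0.5 (observed status is truth,
predicted status is the call) — sensitivity TP/(TP+FN), specificity
TN/(TN+FP), accuracy, Matthews correlation, and AUC computed as the
Mann–Whitney rank statistic with midrank ties. When the observed
statuses are all one class, the undefined classification metrics are
reported as missing rather than zero; categorization uses RMSE only, so
such loci remain usable. The returned coefficients are refitted on all
training samples.

Cross-validated RMSE maps to four accuracy categories:

| category   | RMSE interval      |
|------------|--------------------|
| super_high | RMSE < 0.05        |
| high       | 0.05 ≤ RMSE < 0.1  |
| medium     | 0.1 ≤ RMSE < 0.15  |
| low        | RMSE ≥ 0.15        |

Downstream analyses default to the super_high + high categories.

## Prediction and differential methylation

Stored models applied to a new 450K-style matrix produce a prediction
per model locus × sample, with explicit missingness reasons (feature
probe absent from the platform, feature value missing, model flagged).
Missingness in any required feature propagates cell-wise. Differential
methylation between two sample groups uses Welch's unequal-variance
t-test per probe on the non-missing values, Benjamini–Hochberg
correction across the probes actually tested (skipped probes are
excluded from the family size), and the conjunction rule: a locus is a
DML iff $q < 0.05$ **and** $|\Delta\beta| > 0.1$, with $\Delta\beta$
signed (group1 − group2) and the threshold applied to its absolute
value, since both hyper- and hypomethylation are of interest. A gene is
a DMG iff at least one DML lies in its promoter — TSS200, TSS1500,
5'UTR or 1stExon — judged on the raw per-gene annotation pairs rather
than the single prioritized category, because the 5′→3′ prioritization
(TSS200 > TSS1500 > 5'UTR > 1stExon > Body > 3'UTR > Intergenic)
collapses multi-gene information that the per-gene promoter definition
needs.

## Preprocessing

Beta matrices are quantile normalized across samples before any
correlation or fit, within the cohort at hand (no fixed external
reference): every sample is mapped onto the across-sample mean quantile
curve, missing entries stay missing and the non-missing values are
normalized against the curve by quantile interpolation, with tied
values receiving the mean reference quantile of their tied ranks. At
prediction time the input matrix is normalized independently — the
models transfer across chips without a joint renormalization step.

## The synthetic fixture generator

Real EPIC/450K cohorts cannot ship with a package, so every pipeline
stage is validated on generated fixtures whose ground truth is known.
The generator emulates the statistical structure the method assumes:

* feature-locus betas from the bimodal mixture
  $0.4\,\mathrm{Beta}(0.5, 8) + 0.4\,\mathrm{Beta}(8, 0.5) +
  0.2\,\mathrm{Beta}(2, 2)$, matching the U-shape of real array data
  and exercising the sigmoid's saturating regions;
* each model locus generated from one partner feature locus through a
  planted sigmoid link plus Gaussian noise **on the beta scale**,
  clipped to $[0,1]$ (errors are evaluated on the beta scale, so that
  is where noise belongs). Link slopes are drawn from $w \sim
  U(1.5, 3)$ with intercept $b = -w/2$, which keeps locus means in the
  interior of the beta scale — like partially methylated CpGs — so the
  planted noise sd is the error the model should realize. Steeper links
  would push means against the 0/1 boundaries where clipping shrinks
  the realized error and decouples the planted noise tier from the
  recovered RMSE category;
* per-locus noise sds cycling through the tier set
  $\{0.02, 0.07, 0.12, 0.2\}$, chosen to land in the middle of the four
  RMSE categories;
* manifest geometry mixing adjacent partners (<2 kb), distal partners
  (>2 kb) and partners on other chromosomes, plus a chromosome without
  feature loci so the nearest-neighbour-absent path is exercised;
* flanking sequences in which each model locus's ±200 bp window is a
  mutated copy (per-base rate 0.05) of its partner's window, planting
  recoverable sequence similarity; all other sequence is i.i.d.
  uniform;
* uniform missingness and, for grouped fixtures, a planted mean shift
  $\delta$ on a subset of probes between two sample groups, with
  baseline means from $U(0.25, 0.55)$ so the shift survives clipping.

Default sizes are 60 model loci, 240 feature loci and 120 samples —
large enough for stable correlations and five informative folds, small
enough that the entire build runs in about a second. Because fixtures
are generated directly on the beta scale of an already-normalized
array, builds on them set `normalize_training = FALSE`; renormalizing
an already-commensurable matrix of only a few hundred probes would add
order-statistic noise of a few percent and blur the planted noise
tiers. Real cohorts keep the default `normalize_training = TRUE`.

What passing tests on these fixtures do **not** show: robustness to
probe-level artefacts (Infinium I/II chemistry, detection failures,
cross-reactive probes), batch effects, or biological heterogeneity
between cohorts — the generator plants exactly the co-methylation
structure the method assumes, so recovery rates on fixtures are upper
bounds, not field estimates.

## Numerical and degenerate-input conventions

* Coordinates are 1-based and fully closed throughout; the flank window
  of a CpG at position $p$ is $[p - 200,\ p + 201]$, clipped at
  chromosome ends without padding, and includes the CpG dinucleotide
  itself.
* Zero-variance vectors make a correlation undefined; such candidates
  are excluded from argmax selection, and a model locus with no
  eligible partner is reported in an exclusion list rather than fitted.
* A fold whose training part is degenerate (constant feature) flags the
  whole locus model; flagged models predict nothing and carry a
  `model_flagged` reason.
* Unknown CGI-relation tokens in a manifest map to "open sea" with a
  warning, mirroring manifests that leave the field blank for open-sea
  probes; unknown gene-region tokens are an error.
* Model files are JSON lines with a schema version; coefficients are
  written with 17 significant digits so save/load round-trips are
  lossless.
* Chunked correlation scans (`block_size`) are exact, producing results
  identical to the naive scan; no approximate search is used.

## Limitations

The per-locus strategy assumes the training cohort spans enough
methylation variation for correlations to be estimated; a locus
constant across training samples is unmodelable by construction.
Batch-effect correction is intentionally out of scope — matrices are
expected pre-corrected. Whole-genome (WGBS-scale) expansion would
follow the same partition logic but is not attempted here; WGBS support
means accepting a beta-like matrix computed elsewhere.
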