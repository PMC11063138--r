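---
title: "Reference-protein adjustment for CSF biomarkers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-protein adjustment for CSF biomarkers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfref)
```

## The problem

Cerebrospinal fluid (CSF) biomarker concentrations mix two signals: the
disease process the biomarker is meant to index, and a non-disease,
per-individual offset that moves hundreds of proteins up or down together.
Plausible drivers of that offset are differences in CSF production and
clearance rates and in ventricular volume — in short, how *dilute* an
individual's CSF is. An individual with concentrated CSF can cross a
biomarker positivity cutoff without disease; one with dilute CSF can stay
below it despite disease. The same offset inflates protein–protein and
protein–genotype correlations that have nothing to do with shared biology.

`csfref` implements the full analysis pipeline for this problem: quantify
the shared offset, nominate *reference proteins* that track it without
tracking disease, and evaluate what adjusting key biomarkers (CSF P-tau181,
CSF A-beta-42) for such references does to diagnostic accuracy, AT(N)
classification, and association analyses.

## The mean standardized CSF protein level

All panel values are z-scored per protein, with location and scale always
fitted on training participants only (sample SD, ddof = 1; the convention is
a deliberate choice, it is not dictated by the method). The per-participant
summary of the shared offset is the average z-score over the panel:

$$y_i = \frac{1}{n_{\mathrm{proteins}}} \sum_{j=1}^{n_{\mathrm{proteins}}} z_{ij}.$$

Missing z-scores are excluded from the average (a count-weighted mean)
rather than imputed as zero: zero-imputation would bias $y_i$ toward 0
exactly for the high-missingness participants where the estimate is already
weakest. On complete data the two conventions coincide.

A total-protein (absolute concentration) normalization is deliberately not
offered: absolute totals are dominated by a handful of abundant
blood-derived proteins, whereas the mean standardized level weighs every
protein equally and therefore reflects the brain-derived majority of the
panel.

## The synthetic cohort generator

Access-restricted cohort data cannot ship with a package, so the generator
(`sim_config()` / `generate_cohort()`) is a first-class, tested module that
produces cohorts with the statistical structure the analysis assumes, plus
the full ground truth (`SyntheticTruth`) needed for parameter-recovery
tests. The data-generating model:

* **Latent dilution factor.**
  $d_i = \beta_{age} z(\mathrm{age}_i) + \beta_{sex}\,\mathrm{sex}_i +
  \beta_{vent} z(\mathrm{vent}_i) + \varepsilon_i$, with
  $\varepsilon_i \sim N(0, \sigma_d^2)$. Defaults: $\beta_{age} = 0.3$,
  $\beta_{sex} = 0.3$ (sex coded 1 = male, and the planted direction is
  *higher* level in males), $\beta_{vent} = -0.3$ (larger ventricles, more
  dilute CSF), $\sigma_d = 1.8$.
* **Protein panel.** Protein $j$ of participant $i$ is
  $\mu_j + \lambda_j d_i + \beta^A_j a_i + \beta^T_j t_i + e_{ij}$ with
  $e_{ij} \sim N(0, 0.8^2)$ NPX (log2) units. Loadings $\lambda_j$ come in
  clusters (default 10 clusters, loadings decreasing from 1 to 0.05 with
  within-cluster jitter 0.05). The cluster with the highest loading is the
  planted *reference cluster*: zero disease effects, maximal dilution
  tracking.
* **Disease burdens.** Amyloid burden $a_i$ is a standardized two-component
  mixture (non-accumulators vs accumulators), because amyloid PET is
  strongly bimodal in real cohorts; a unimodal Gaussian puts far too many
  participants at the positivity threshold and makes the CSF ratio
  misclassify a quarter of them. Tau burden is modeled *downstream* of
  amyloid, $t_i = \rho\,\mathrm{std}(\max(a_i - q_A, 0)) +
  \sqrt{1-\rho^2}\,u_i$ with $\rho = 0.95$: tau-PET positivity virtually
  requires amyloid positivity in AD cohorts, and with independent or merely
  correlated Gaussian burdens the simulated population contains so many
  genuinely tau-positive amyloid-negative people that no cutoff adjustment
  could ever shrink the A-T+ cell.
* **Designated biomarkers.** One protein in the second-loading cluster
  carries the tau effect (+1.8 NPX per unit $t$, the P-tau181 analogue), one
  in the third carries the amyloid effect (-3.0 NPX per unit $a$, the
  A-beta-42 analogue), and the first two reference-cluster proteins play
  A-beta-40 and the P-tau181-specific reference. Each main biomarker also
  shares a *pathway factor* (SD 0.8) with its specific reference — the
  A-beta-42/A-beta-40 co-secretion analogue. This term matters: without it
  the panel-wide mean level is mathematically the best achievable dilution
  proxy (it averages away all protein noise), and no single reference could
  ever outperform it. With a pathway share, a specific reference removes
  covariation the mean level cannot see. The magnitude follows from the
  projection arithmetic: with $\lambda_{pt}\sigma_d \approx 1.5$ and panel
  noise 0.8, a pathway SD near 0.8 makes the single-reference residual
  smaller than the mean-level residual — the regime in which searching for
  specific references is worthwhile at all.
* **Concentration-scale assays.** The cohort table carries
  immunoassay-style pg/ml columns built from the same latent components with
  their own smaller noise (SD 0.4): clinical assays are far more precise
  than a 3000-plex panel. The two amyloid peptides share a single dilution
  loading so that their ratio is dilution-free — dilution is a volume
  effect and cancels in a ratio of co-secreted peptides. Scales are
  calibrated so the conventional cutoffs (P-tau181 21.8 pg/ml, ratio 0.08,
  tau-PET SUVR 1.36, centiloid 20) sit at the configured prevalence
  quantiles (tau 27%, amyloid 33%), making the default `atn_config()`
  directly meaningful on simulated cohorts.
* **Outcomes.** PET positivity thresholds noisy burdens at the prevalence
  quantiles (PET noise SD 0.25); conversion to dementia is generated from
  the tau burden with extra noise at half the tau prevalence; below-LOD
  censoring marks values *missing* (never imputed at half the detection
  limit), matching the treatment of detectability as missing frequency.

What the generator deliberately does **not** emulate: longitudinal
trajectories, batch/plate effects, heavy-tailed or skewed NPX noise,
assay-specific saturation, and panel bridging. Tests passing on these
cohorts show the pipeline recovers planted structure under its own
assumptions; they do not certify behavior under real-data pathologies
outside that list.

## Reference search

Proteins are embedded as points in participant space (each protein's
coordinates are its z-scores across participants) with exact t-SNE —
perplexity 30 by default (the conventional middle of the 5–50 range),
deterministic PCA initialization plus seeded jitter, early exaggeration 4
for 100 of 500 iterations, learning rate 200, adaptive gains. K-means
(K = 20) partitions the embedding. The "semi-supervised" manual step of
this kind of analysis (an analyst joining visually overlapping regions) is
operationalized as `merge_overrides`: an
explicit, logged list of label pairs to collapse, so that a run is fully
reproducible from its configuration rather than from an analyst's
interactive choices (t-SNE layouts are notoriously irreproducible, which is
exactly why the package pins the step down).

Six per-protein metric maps guide nomination: absolute standardized
association (age/sex-adjusted) with the mean level and with ventricular
volume; association with P-tau181 and A-beta-42 among cognitively
unimpaired amyloid-negative participants (diagnosis NC/SCD and ratio at or
above 0.08 — the subset where biomarker covariation is non-disease by
construction); and the 10-fold cross-validated AUC when the protein serves
as the reference covariate in each of the two search models. One fold
assignment is shared across all proteins so per-protein AUCs are paired.
Min-max scaling maps each criterion to [0, 1]; a constant map degenerates
to all-zeros with a warning rather than 0/0.

Candidate selection applies three criteria — membership in
the winning cluster, AUC gain in *both* search models, presence in the
validation panel — ranked by mean AUC gain. The automatic cluster
nomination ignores clusters below 5 proteins (a singleton cluster's "mean"
AUC is one noisy draw). The conversion model (P-tau181 predicting dementia
conversion) is never used for search, only for validation.

## Evaluation machinery

* **AUC** is the midrank Mann-Whitney form (ties count 1/2).
* **Models** are unpenalized maximum-likelihood logistic regressions,
  `outcome ~ predictor + reference + age + sex`, with predictors
  standardized inside training folds. The reference enters as a covariate,
  not a ratio: the covariate form is what yields an adjusted AT(N) cutoff
  that is *linear* in the reference (a ratio mode remains available via the
  A-beta-42/A-beta-40 convention upstream).
* **Schemes.** 10-fold cross-validation for exploration; refit-on-train /
  evaluate-once-on-test for held-out evaluation; out-of-bag bootstrap
  (resample to full size, evaluate on the never-selected ~36.8%) for
  external-style validation, with iterations sharing resamples across
  references so AUC differences are paired.
* **Comparison.** One-sided bootstrap ROC test (resample participants,
  n_iter = 2000), `p = (k + 1)/(n_used + 1)` where k counts iterations with
  AUC difference at or below zero; the +1 correction keeps p away from 0,
  and identical score vectors give p = 1 by the stated convention.
  Resamples that lose an outcome class are skipped and counted.
  Benjamini-Hochberg adjustment is applied across all comparisons of a
  grid. Composite references use the first right-singular direction of the
  column-standardized candidate block, sign-fixed to correlate positively
  with the candidates' mean.

## AT(N) classification

Strict-inequality conventions throughout: A+ when ratio < 0.08; T+ when
P-tau181 > 21.8 pg/ml (unadjusted); tau-PET positive when SUVR > 1.36;
amyloid-PET positive when centiloid > 20. The reference-adjusted boundary
comes from `pet ~ ptau + reference_z` logistic regression; a line of
constant predicted probability is linear in (ptau, reference), giving
`ptau > a + b * reference_z` with the reference in z-units and P-tau181 in
pg/ml. Three operating rules are implemented. The default is the model's
0.5-probability boundary. An operating point that instead matches the
unadjusted cutoff's specificity is available but cannot shrink the A-T+
cell even in principle — it fixes the false-positive count by construction
— so it is not the default. Youden's J is the third option. In both
concordance matrices the A axis always comes from the CSF ratio; only the T
axis differs between CSF and PET groupings.

## Association analyses

Partial correlations are Pearson correlations of covariate-residualized
variables, computed on listwise-complete observations across the whole
protein block (the pairwise-complete alternative would make coefficients of
one matrix incomparable). Paired with/without-reference matrices are always
produced together, ordered by decreasing association with the mean level.
ANCOVA group comparisons use cell-means coding so pairwise contrasts come
straight from the coefficient covariance (pooled residual variance), BH
adjusted per protein. pQTL mechanics use Hardy-Weinberg-style dosages and
plain linear models refit with the reference added; ten synthetic standard
normal "genetic principal components" stand in for real ones, since only
the adjustment mechanics are under test. The bootstrap enrichment test
draws equal-size subsets from the background without replacement and scores
two-sided extremeness around the null center with the same +1 correction.

## Numerical choices and degenerate inputs

* Sample SD (ddof = 1) everywhere a scale is estimated.
* Zero-variance proteins are an error at standardization (they cannot be
  z-scored), named individually.
* Ordering ties (candidate ranking, level-association ordering) break by
  protein id for determinism.
* Folds are plain random draws, re-drawn stratified by outcome only if a
  training fold would lose a class.
* The detectability filter keeps proteins with missing frequency strictly
  below the threshold; fully observed proteins always survive, including at
  a threshold of zero.
* Every stochastic stage takes an explicit seed; `run_pipeline()` writes a
  machine-readable summary that is byte-identical across reruns of one
  configuration.

## Problem sizes

The test fixtures run three canned conditions (null / dilution-only /
dilution+disease) at 400 participants x 150 proteins in 6 clusters of 25 —
large enough for every directional effect to be stable across seeds, small
enough for the whole suite to run in minutes. The generator's default is
a full-scale 658 participants x 500 proteins x 10 clusters (scaled down
from the 2944-protein panel), which is what `scripts/acceptance.R` runs.
Calibration checks use 500 replicates at a reduced 500 bootstrap
iterations; type-I error is asserted within binomial slack of the nominal
5%.

## Known limitations

The generator's linear-Gaussian panel cannot produce the skewed,
heteroscedastic NPX distributions of real multiplexed assays, and its
dilution factor is a single global scalar — real inter-individual
variability likely mixes several physiological processes with
protein-specific elasticities. t-SNE layouts and cluster numberings are
not comparable across datasets; only cluster *content* relative to the
metric maps is meaningful. Adjusted-boundary constants derived on
synthetic cohorts are meaningful only in sign and in the direction of the
concordance change, never as particular numbers.
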