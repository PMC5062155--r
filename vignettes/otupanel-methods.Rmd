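---
title: "Methods: subject-blocked random-forest OTU panels for Crohn's disease activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subject-blocked random-forest OTU panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Crohn's disease alternates between flares of active intestinal inflammation
and remission. Endoscopy, the reference for assessing mucosal inflammation,
is invasive; clinical scores (Harvey-Bradshaw index, HBI) and biochemical
markers (serum C-reactive protein, CRP; fecal calprotectin, FC) are
imperfect surrogates. Because the gut microbiota shifts with inflammation,
the *community structure* of the fecal microbiota — a panel of operational
taxonomic units (OTUs) rather than any single taxon — is a candidate
non-invasive activity marker. This package implements that analysis as a
reusable, fully tested pipeline: from an OTU count table plus clinical
metadata to an activity classifier with honest, subject-blocked validation.

## Activity labeling

A sample is **active** iff FC > 250 µg/g. It is in **remission** iff
HBI ≤ 4 *and* CRP < 5 mg/l *and* FC < 100 µg/g. All inequalities are exactly
as stated; FC > 250 suffices for active on its own. Two edge policies were
genuinely open and are resolved as follows:

* Samples with FC in [100, 250] and quiescent clinical scores satisfy
  neither definition. They are labeled `indeterminate` and dropped from
  modeling (the reference dataset contains only labeled samples, so the
  case simply never arose there).
* Samples collected within "one month" of an antibiotic course are
  `excluded` before labeling; one month is fixed at 30 days because a
  calendar month is not testable.

## Preprocessing

The fixed order is: singleton removal → rarefaction → group-prevalence
filter → inverse-hyperbolic-sine transform → per-subject mean centering.

* **Rarefaction** to 4,930 reads/sample is done *without replacement*
  (multivariate hypergeometric), the standard behavior of the QIIME/mothur
  lineage; the source text does not specify the sampler. Samples under the
  depth are dropped and logged, never silently. Note that singleton removal
  can push a sample that started just above the depth below it.
* **Prevalence filter**: an OTU is kept iff detected (count > 0) in ≥ 20 %
  of active samples *or* ≥ 20 % of remission samples. The comparison is
  inclusive; boundary behavior was unstated. The filter runs on the
  rarefied table, matching the stated workflow order ("prior to actual RF
  analyses").
* **asinh transform**, `y = log(x + sqrt(x² + 1))`: defined at zero,
  strictly monotone, ~logarithmic for large counts; suits sparse skewed
  counts without a pseudocount.
* **Per-subject centering** subtracts each subject's mean profile so the
  classifier sees within-patient change, not inter-individual composition.
  Subjects with a single sample become all-zero rows and are retained
  (the reference cohort kept 14 single-sample patients). Centering uses
  only a subject's own samples, so it is independent of any
  train/validation split by construction — subjects never straddle splits.

## The two-stage random forest

There is no random-forest package in the supported dependency set, so the
forest is implemented in this package (C++/Rcpp): CART trees grown to
purity on bootstrap resamples, Gini impurity, `mtry = √p` candidate
features per node, mean-decrease-in-impurity (MDI) importance, and
terminal-leaf export for proximities. Forests are seeded by a private
Mersenne Twister, independent of R's RNG state.

**Split plans.** Every subset keeps all samples of a subject on one side.
Subjects are shuffled; the training side takes subjects greedily until it
first holds ≥ 80 % of all samples; the rest validate. Subsets are distinct
(re-drawn on collision). If the greedy pass would empty the validation
side (possible with very few subjects), the last subject added is moved to
validation so both sides are non-empty.

**Stage 1 (panel selection, 90 subsets × 700 trees).** One forest per
subset, fitted on the training side only; per-OTU MDI importance is
averaged arithmetically across subsets (the aggregation rule was
unstated); the top 50 OTUs form the panel, ties broken lexicographically
by OTU id so results are reproducible. The importance measure itself was
unnamed in the source; MDI is the default and a hold-out permutation
importance (accuracy drop on each subset's validation samples) is
available behind a flag.

**Stage 2 (classification, 300 subsets × 700 trees).** One forest per
subset on the panel features; each forest classifies its validation
samples (forest-internal majority; an exact tree tie counts as remission,
a deterministic rule that avoids silent bias). A sample's **vote rate** is
the fraction of models calling it active among models where it sat in
validation; samples never validated are reported, not dropped. Hard labels
follow the 0.5 majority; a vote rate of exactly 0.5 is reported
`indeterminate` (the reference run observed none). The ROC sweeps a
threshold over pooled vote rates; AUC is computed both by trapezoid and as
the Mann-Whitney rank statistic, and the test suite asserts their
agreement to 1e-10. Sensitivity/specificity are taken at 0.5;
PPV/NPV follow from the confusion counts.

**Proximities.** proximity(i, j) = fraction of trees in which i and j
share a terminal node, averaged over stage-2 models, computed by dropping
*all* samples (in-bag and out-of-bag jointly — the finer distinction was
unstated) down every tree. 1 − proximity is embedded by classical MDS
(PCA of the double-centered squared dissimilarities). Because proximity
accumulation is quadratic in samples, the pipeline uses a configurable
subset of stage-2 models (default 30); coordinates stabilize well before
that.

## Supporting statistics

* **Phylum prevalence**: a phylum is present in a sample iff any of its
  OTUs has a positive count; unparseable lineages pool as "unclassified".
* **2×2 contrasts** use the uncorrected Pearson chi-square (1 df). The
  source did not name its test; the uncorrected chi-square reproduces both
  printed baseline p-values (0.01 and 0.003) from the reconstructed
  tables, which is why it is the default; Fisher's exact test is a flag.
* **Friedman screen**: per panel OTU, observations are averaged per
  (subject, factor level) cell, only subjects observed under every level
  are usable blocks, and the Friedman statistic is tested against its
  chi-square approximation with Benjamini-Hochberg FDR across OTUs
  (cut-off 0.05). For between-subject factors (e.g. disease location) a
  within-block design is ill-posed; the implementation is the generic
  within-block version and the printed per-factor p-values are not
  reproduction targets. All-tied data report statistic 0, p = 1.
* **Panel-FC correlation**: with a univariate target the first canonical
  correlation equals the multiple correlation of FC on the panel matrix,
  computed by least squares. Fifty predictors on ~190 samples overfit, so
  R is optimistic by construction; inference rests on a permutation test
  (p = (1 + #{R\* ≥ R}) / (1 + B)).

## The synthetic cohort generator

The generator exists so every downstream stage is testable without patient
data. Its defaults are the stated study design, frozen once:

| parameter | default | rationale |
|---|---|---|
| subjects | 71 | study design |
| samples/subject | 1–8, empirical distribution | study's Table of per-subject counts (~194 samples in expectation) |
| OTUs | 2000 | same order as the study's post-filter table |
| discriminatory OTUs | 50 | size of the published panel |
| effect size | 4× | free parameter; the source publishes no effect sizes |
| subject dispersion | 50 | strong inter-individual variation, the regime motivating per-subject centering |
| depth | N(8333, 1500²), truncated ≥ 4930 | study's mean depth; truncation at the rarefaction depth so no default sample is dropped (`allow_shallow` opens the exclusion path) |
| sparsity | 0.3 | per-subject structural absence probability; realized zero-cell fraction is far higher (~0.9) because multinomial sampling adds zeros |
| active fraction | 0.5 | 97/194 |

Mechanism: a global log-normal (sdlog 2) abundance profile; per subject a
Dirichlet draw around it (concentration = dispersion × profile) with
structural zero-masking; states assigned to hit the active fraction
exactly; in active samples the discriminatory OTUs' relative abundances
are multiplied (half) or divided (half) by the effect size — mirroring the
mixed enrichment directions of the published panel — and renormalized;
multinomial counts at the truncated-normal depth. Discriminatory OTUs are
drawn from OTUs with expected count ≥ 5 at the rarefaction depth so a
planted effect is in principle detectable. Clinical values are drawn
inside the labeling regions (active FC ∈ (259, 4900); remission
HBI ∈ 0–4, CRP ∈ (0, 4.7), FC ∈ (14, 98), the published ranges), so the
labeling module recovers the planted state exactly — tested exhaustively.

What the generator does **not** emulate: phylogenetic correlation between
OTUs, sequencing error and chimeras, longitudinal autocorrelation within a
subject (each sample re-draws from the subject baseline), or
covariate-microbiome dependence (medication flags are independent noise).
A green synthetic test therefore establishes algorithmic correctness and
statistical calibration, not clinical performance.

## Determinism and numerics

One user seed fans out to per-stage sub-seeds via a fixed affine map
(stage constants × 104729, modulo 2³¹ − 1, exact in doubles), so adding a
stage never perturbs earlier stages' draws. C++ forests take explicit
integer seeds derived per subset. Config files are JSON (no TOML/YAML
reader is available in the supported set; JSON round-trips losslessly,
which is the contract), and all outputs carry a 32-bit FNV-1a hash of the
serialized config for provenance. Quantiles use linear interpolation
(R type 7); the quantile convention was unstated. Chao1 uses the
bias-corrected form S + F₁(F₁−1)/(2(F₂+1)), defined when F₂ = 0; the
classic form is a flag. Shannon entropy is in nats — the published medians
(~7.0 with ~10³ OTUs) are only consistent with the natural log.

## Known limitations

* **Two-stage selection optimism.** Stage-1 subsets span all subjects, so
  every stage-2 validation sample helped select the panel. Under a null
  cohort (effect size 1) the *stage-2 classifier with a label-blind panel*
  is well calibrated (mean AUC ≈ 0.5, asserted by the acceptance suite),
  but the *full two-stage pipeline* is measurably optimistic (the suite
  asserts mean null AUC > 0.52). This bias is inherent to the published
  design, not to this implementation; truly unbiased performance numbers
  would require selecting the panel inside each stage-2 training fold.
* **Weak planted signals near the detectability floor.** With exactly as
  many panel slots as planted OTUs, recovery plateaus below 80 % because
  low-abundance planted OTUs genuinely cannot out-rank noise; with the
  published 50-slot panel the recovery criterion is met. Generator
  parameters were frozen before measurement and not tuned toward either
  outcome.
* The published headline numbers (AUC 0.82, sens 0.79, spec 0.73) are
  properties of the study's own 194-sample dataset and are not
  reproducible without it; only their internal arithmetic (PPV/NPV, the
  baseline 2×2 p-values, prevalence percentages) is reproduced here.
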