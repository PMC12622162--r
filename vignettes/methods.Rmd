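---
title: "Methods: functional-evidence variant effect prediction, ACMG calibration, and genetic epidemiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional-evidence variant effect prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vepkit)
```

## The problem and the model

Most computational predictors of missense variant effect learn from clinical
labels or population allele frequencies. Both choices couple the predictor to
the very evidence it is later combined with — a variant judged pathogenic
partly *because* a tool scored it high can reappear in that tool's training
set, inflating every downstream benchmark (training circularity), and
allele-frequency-informed scores double-count the ACMG BS1/BA1 criteria.
`vepkit` implements the alternative: binary gradient-boosted classifiers
trained on *functional* evidence (assay measurements, curated and text-mined
functional annotations), with explicit machinery to keep clinical and
population information out of the features and the evaluation.

Three feature regimes bound the dependence on other predictors:

* **CTI** — every catalog feature, including clinical-trained predictor
  scores;
* **CTE** — predictor scores trained on clinical labels removed;
* **SP** — all predictor scores removed, leaving conservation, structural,
  residue-constraint, substitution-matrix, protein-language-model and
  gene-level features.

By construction SP ⊆ CTE ⊆ CTI, which the test suite asserts on randomized
catalogs.

## Dataset construction

**Assay calibration.** Each assay study (a per-gene table of continuous
scores) is calibrated against binary clinical labels on the overlapping
variants. Orientation is resolved by flipping the scale when the rank AUC is
below 0.5; separation is tested with a one-sided Wilcoxon rank-sum test; a
study is accepted when its p-value clears the Bonferroni share `alpha /
n_studies` and the labeled overlap reaches `min_overlap` (default 10).
Because every step is rank-based, the procedure is invariant to monotone
transformations of the assay scale. Accepted studies are binarized at the
balanced-accuracy-optimal cut, with ties broken toward the midpoint of the
tying cuts (a midpoint is the least arbitrary representative of an
indifference interval; the model's decision-threshold optimizer instead takes
the *smallest* tying cut so that thresholds are reproducible to the data
resolution).

**Merging.** Sources merge with precedence `curated > mave > text_mined`.
Label conflicts *within* one tier are dropped outright — a variant that one
curated study calls damaging and another calls neutral is not worth a vote —
while a higher tier simply overrides a lower one. Proxy-benign population
variants enter only when their key appears in no labeled source, weighted by
`(log10 AF − min log10 AF) / (max log10 AF − min log10 AF)` so that the
rarest proxy carries weight 0 and the most common weight 1 (rarity is the
weakest evidence of benignity). A degenerate all-equal input gets weight 1.

**Clinical mirror.** The clinical builder keeps records with at least two
review stars and a conclusive class (pathogenic / likely pathogenic / benign
/ likely benign), drops predicted splice disruptors (splice score strictly
greater than 0.2 — a score exactly at the cutoff is kept), and balances per
gene. Balancing down-samples the majority class to the minority count within
each gene, seeded; single-class genes are dropped by default. The
`keep_capped` policy retains them capped at the median per-class size of the
balanced genes — the cap value is this package's choice, since a cap must
come from somewhere and the balanced genes define the typical per-gene mass.

## Circularity elimination

The tool registry maps every predictor feature to its training variants and
component tools. The effective training set of a tool is the union over all
tools reachable in the component graph (computed by fixed-point union, tested
against an independent depth-first-search oracle). `mask_circular_scores()`
sets to missing every (variant, predictor-score) cell whose variant lies in
the feature's effective set; masked cells become ordinary missing values and
are eligible for imputation, since trees and imputers see only a missing
entry, not the reason for it. Tools with unknown training sets are flagged
`training_unknown`: they stay in the model features but are excluded from
benchmark comparisons. Trained models additionally record their own training
keys and refuse to score them (`EXCLUDED_TRAINING`), so no benchmark can ever
feed a model its own training variants.

## Features and imputation

The four protein-language-model features are derived from per-position
log-likelihoods and a mean embedding for the wild-type and mutant sequences:
mean log-likelihood difference, perplexity difference
(`perplexity = exp(−mean log-likelihood)`), Euclidean embedding shift, and
the site-local log-likelihood difference. Directions are fixed so that larger
values mean a less plausible mutant. The three difference features are
antisymmetric under swapping wild type and mutant; the embedding shift is
symmetric. Statistics come from a provider interface — any deterministic
function from sequence to statistics works, and the tests use synthetic
providers; wiring a real protein language model is an optional adapter.

Features whose *missingness* differs between classes leak labels through the
missing-value pattern. `flag_biased_missingness()` applies a two-proportion
test per feature at `alpha = 0.01` (fully missing features are flagged
unconditionally); flagged features are imputed by gradient-boosted regressors
trained on unlabeled background variants only, using all other features as
predictors. Labels never enter the imputation, observed cells are never
altered, and imputed cells are tagged in the output's provenance attribute.
Imputation models are trained once on the full catalog rather than per
regime: the regressors see no labels, so regime separation would change
nothing except compute. Recovering a deterministic relation to the tested
tolerance needs a few thousand observed background rows; the tests use 3,000
(real pipelines would use orders of magnitude more unlabeled variants).

## Model training

Classifiers are gradient-boosted tree ensembles (xgboost, single-threaded for
bit-reproducibility). The split is stratified by label (default 90/10) so
small fixtures keep both classes in the holdout. Hyperparameters are drawn by
seeded random search — depth 3–8, learning rate 0.02–0.3 (log-uniform),
min-child-weight 1–10, row/column subsampling 0.6–1, L2 penalty 0–5 — with
early stopping on holdout AUC; the best configuration is refit on the
training split only. Refitting on train+holdout after selection would
invalidate the reported holdout metrics, so the holdout stays untouched; the
manifest records seed, trials, split, parameters and the excluded training
keys. The decision threshold maximizes balanced accuracy over an exhaustive
sweep of score midpoints.

## ACMG calibration

Evidence strength follows the Bayesian points framework: with prior
pathogenicity probability 0.10 and a very-strong likelihood ratio ceiling of
350, graded cutoffs are the geometric roots `350^(1/8)` (supporting),
`350^(1/4)` (moderate) and `350^(1/2)` (strong), with reciprocals on the
benign side; PP3/BP4 are capped at strong. Point values are ±1/±2/±4 (+8 for
very strong pathogenic), with bands P ≥ 10, LP 6–9, VUS 0–5, LB −6…−1,
B ≤ −7. The VUS sub-bands (high 4–5, mid 2–3, low 0–1) are this package's
partition of the uncertain range; "conclusiveness" is 1 minus the VUS-mid
fraction.

The local likelihood ratio along the score axis is estimated by a penalized
logistic spline (REML smoothness selection) of label on score, converted to a
likelihood ratio by dividing out the calibration set's class balance —
equivalent to re-weighting the empirical odds to the target prior. Raw
fixed-count sliding windows were evaluated first and rejected: with 500-point
windows on 10,000 Gaussian-mixture scores the tail windows showed 25–40%
relative LR error across seeds, while the spline stays within a few percent
of the analytic ratio. Fitted probabilities are clipped away from 0/1, the LR
is capped at the ceiling and its reciprocal, and isotonic regression on the
log scale enforces monotonicity — evidence strength should never weaken as
the score grows. Runs of equal monotonized LR become score intervals (local
PPV/NPV at the target prior); lookups clamp out-of-range scores to the
nearest interval. `window_min` (default 100) sets the minimum calibration
mass (`n >= 2 * window_min`) and caps spline flexibility at roughly one
degree of freedom per `window_min` variants. Degenerate score support (fewer
than four distinct values) falls back to a constant LR of the global odds.

## Genetic epidemiology

Cumulative allele frequency is the clamped sum of qualifying variants' allele
frequencies. Under Hardy–Weinberg: autosomal carrier frequency is
`1 − (1 − CAF)²`; AR genetic prevalence is `CAF²`; AD prevalence equals the
carrier frequency (any carrier is an affected genotype); X-linked prevalences
are `CAF(CAF+1)/2` (XLR) and `(1 − CAF)CAF + CAF(CAF+1)/2` (XLD), pooling
hemizygous males and homozygous (plus, for XLD, heterozygous) females at a
50/50 sex ratio. The X-linked *carrier* frequency uses the same pooling:
`½·CAF + ½·(1 − (1 − CAF)²)`. Penetrance is Bayes' rule
`P(D|C) = P(D)·P(C|D)/P(C)`, clamped at 1 with a warning because noisy
carrier estimates can push the ratio above 1. Cohort carriage assumes
independence across genes (`p_any = 1 − Π(1 − CrF)`), and GP ranking is a
dense descending rank with ties sharing the better rank.

The 13 association masks are: P; P+LP; P+LP+VUS-high; those plus
predictor-damaging missense; predictor-damaging missense alone (any class,
score above 0.631 — the default corresponds to a trained model's optimized
decision threshold and is overridable); predicted loss-of-function strata by
PVS1 strength (very strong / strong / moderate / supporting) and their
cumulative unions; and non-splice-altering synonymous variants (splice score
below 0.2), the negative-control mask. Each mask is crossed with four
allele-frequency strata (≤ 0.5, ≤ 0.1, ≤ 0.01, allele count = 1). All four
ACMG-category masks are emitted; selecting a single representative is left to
the caller as a reporting convention.

## Benchmarking

AUC uses the Mann–Whitney midrank formulation (ties count ½), verified
against a brute-force all-pairs oracle and an independent ROC implementation.
Agreement with continuous assay scores is the R² of a penalized thin-plate
spline regression (generalized cross-validation) of assay on predictor score
— a smooth-regression equivalence class rather than any specific basis —
with tool–study pairs under 10 complete observations excluded and
zero-variance assays defined as R² = 0. Per-tool summaries average over
eligible studies only; a tool with no eligible study is reported
not-evaluable rather than zero.

## The synthetic generator

The generator fixes the study conditions for every test: by default 20 genes
× 100 variants with balanced Bernoulli labels, 25 features across the seven
catalog categories of which 5 are informative with a 2-sd class-mean shift
(informative features are placed in non-predictor categories first so that
every regime keeps signal), 5% missing-completely-at-random cells plus two
features with class-biased missingness (40% vs 5%), per-gene assay studies
with Gaussian noise and random orientation flips, log-uniform allele
frequencies on [1e-6, 1e-2] with 10% singletons, and random acyclic tool
registries. A single master seed governs everything; each operation derives
its sub-stream as `seed + offset` (variants +1, features +2, assays +3,
population +4, clinical table +5), so composite fixtures are reproducible
piecewise.

What the generator does *not* emulate: real linkage between features (all
noise is independent Gaussian), realistic allele-frequency spectra or
ancestry structure, gene-length variation, assay-specific error models, or
real protein sequences. Passing tests therefore demonstrate that the
machinery is correct under known ground truth — recovery of informative
features, correct masking and calibration, deterministic pipelines — not
that any particular real-data accuracy will be achieved.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberate desk scale: 2,000
variants and 25 features for model training (15–25 search trials), 10,000
scores for calibration recovery, 20-seed null batteries at 2 trials, and a
small 6-gene × 40-variant preset for the end-to-end command-line runs. Other
fixed numerical choices: Haldane-style clipping of fitted probabilities
before odds conversion; smallest-cut tie-breaking for decision thresholds and
midpoint tie-breaking for assay binarization (rationales above); CAF and
penetrance clamping with warnings rather than errors; masked cells
indistinguishable from ordinarily missing ones by design.

## Known limitations

The classifier predicts a binary damaging/neutral state: no direction
(loss vs gain of function) and no effect magnitude. AD genetic prevalence
equals carrier frequency, an upper bound that ignores reduced penetrance.
The X-linked pooling assumes an exact 50/50 sex ratio. Calibration assumes
the score–label relation is smooth; a genuinely discontinuous score would be
over-smoothed. The imputation regressors assume the background and target
matrices share a feature distribution; a shifted background silently biases
imputed cells toward its own marginal.
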