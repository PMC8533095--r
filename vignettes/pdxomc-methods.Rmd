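---
title: "Predicting PDX drug response with optimal-model-complexity random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting PDX drug response with optimal-model-complexity random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patient-derived xenografts (PDXs) — patient tumours engrafted in mice — let
one measure the in vivo response of a molecularly profiled tumour to a drug.
A pharmacogenomic PDX cohort therefore supports a question at the heart of
precision oncology: from a tumour's molecular profile, can we predict whether
it will respond to a given treatment, and which genes carry that signal?

The dominant clinical practice is the *single-gene marker*: call a tumour
sensitive iff a specific gene carries an actionable mutation. Even approved
markers can be weak. The package's worked example is the EGFR-mutation marker
of erlotinib response in non-small-cell lung cancer: of 100 treated patients,
19 were EGFR-mutant but only 3 of those responded, while 6 of the 81
wild-type patients responded too. As a classifier this marker has
TP = 3, FP = 16, FN = 6, TN = 75 — precision 16%, recall 33%, and a Matthews
correlation coefficient (MCC) of 0.11, barely above chance.

`pdxomc` implements, end to end, a methodology for doing better with machine
learning while keeping gene lists short: class-weighted random forests with
an *optimal model complexity* (OMC) wrapper that selects how many of the
top-ranked features a case actually needs, evaluated by nested leave-one-out
cross-validation (LOOCV) against the single-gene marker and two random
baselines.

## Data model

Four molecular profiles are supported, mirroring the tab layout of the public
PDX encyclopedia workbook, read from delimited text (gene × sample, header =
sample ids, first column = gene symbol):

* **SNV** — binary: a gene's feature is 1 iff at least one single-nucleotide
  variant was detected in it for that PDX (one feature per gene, not per
  variant, which keeps the matrix dense);
* **CN** — real-valued copy number, used as provided;
* **CNA** — the binarisation of CN: 1 iff copy number is ≥ 8 (strong
  amplification), in [5, 8) (moderate amplification), or ≤ 0.8 (deletion);
  the three thresholds are a `cna_thresholds` configuration object;
* **GEX** — gene expression on the FPKM scale, used as provided, with no log
  transform or normalisation.

`merge_profiles()` concatenates profiles over their common samples with
profile-prefixed feature ids, so the same gene arriving through two profiles
stays two distinct features.

Treatment response is the mRECIST-style categorisation of percentage
tumour-volume change (%ΔTVol) curves. Two curve statistics drive it:
*BestResponse*, the minimum %ΔTVol at or after `min_day` (default day 10),
and *BestAvgResponse*, the minimum over eligible days of the running mean of
%ΔTVol from the first post-baseline measurement. The default rule cascade is
CR if BestResponse < −95 and BestAvgResponse < −40; else PR if < −50 and
< −20; else SD if < 35 and < 30; else PD — all comparisons strict, so a
boundary curve falls to the less responsive class. Where both a retrieved
category (from a processed table) and a recalculated one exist and disagree,
the recalculated one wins, so one rule set governs the whole cohort.
Categories collapse to the binary modelling classes: CR/PR/SD = sensitive
(responder), PD = resistant. Every threshold is configuration, not code; the
eligibility window applies to both the running-average start and the minimum
search (the source material leaves this open; applying it to both is the
stricter reading and is flagged for audit).

A *case* is one treatment × cancer type × profile: `build_case_dataset()`
intersects the profiled and treated PDXs and flags (never silently drops)
cases below the inclusion threshold (default 35 PDXs; no optimality claim
attaches to that number) or with a single response class.

## Models

All four model families share the evaluation contract: per LOOCV fold they
emit a sensitivity score in [0, 1], thresholded at 0.5 (configurable) into a
class call; pooled fold predictions give one MCC (with precision, recall, F1,
specificity and AUC) per pass.

**RF-all.** A random forest over all features with 1000 trees (default),
`mtry = floor(sqrt(p))`, and class weighting: each class's misclassification
penalty is the *other* class's prevalence, so the minority class carries the
heavier penalty. No per-case hyperparameter tuning is done — forest tuning
buys little at a large compute cost on data of this shape.

**RF-OMC.** Three modules: (1) rank all features of the training fold by
univariate association with response — two-sided Fisher's exact tests for
binary features, two-sided Welch t-tests for real-valued ones; (2) for every
candidate size k ∈ {2, …, ⌊n/2⌋} train the forest on the top-k features and
measure its LOOCV MCC within the training fold, plus one candidate using all
features (to detect cases needing more than n/2); (3) select the candidate
with the highest inner MCC. The n/2 cap guarantees at least two training
samples per considered feature. Ties select the smallest subset — parsimony
is the point of OMC — and an NA inner MCC loses to any number. Features are
ranked once per outer training fold and reused across that fold's inner
LOOCV (a stricter re-rank-per-inner-fold mode is available by flag; outer
estimates are leakage-free either way because the outer test sample never
enters the ranking). Ranking keeps both effect directions: forests can
exploit markers of resistance as well as sensitivity.

**Single-gene marker.** Per fold, a Fisher scan over all genes of the binary
profile; the lowest-p gene among sensitising mutations (ϕ > 0) becomes the
marker, and the held-out PDX is predicted sensitive iff mutated in it. Genes
constant in the training fold get p = 1 and are unelectable; if no gene has
ϕ > 0 the fold predicts resistant. After evaluation,
`final_single_gene_marker()` refits on all samples so the marker is usable
on forthcoming tumours.

**Random baselines.** The prior-probability model draws a uniform number per
fold and predicts sensitive when it falls below the training-fold sensitive
proportion; the random-feature control draws k features at random and runs
the standard forest LOOCV on them, mirroring the question "are the
OMC-selected k features better than any k features?".

### Why nested cross-validation

Model selection (here: the subset size) optimises the inner LOOCV MCC, which
is therefore optimistically biased — on pure-noise data the best of ~n/2
candidates will look well above chance. The outer LOOCV never lets the
held-out PDX influence ranking, selection or training, so its pooled MCC is
unbiased. The test suite demonstrates both halves on label-permuted
cohorts: inflated inner maxima, near-zero outer estimates. Models without
selection (RF-all, single-gene, random baselines) use standard LOOCV.

## Statistical conventions

* MCC is NA whenever one of its four marginal sums is zero (the classifier
  or the truth lacks a class); NA is never coerced to 0.
* Precision/recall are NA on zero denominators; F1 is NA when either
  ingredient is NA and 0 when both are 0.
* Two-sided Fisher p-values sum the probabilities of all tables (same
  margins) no more probable than the observed one, with the customary
  (1 + 1e−7) relative tolerance — the convention of `stats::fisher.test`,
  against which the implementation is cross-checked (it is vectorised
  in-package because per-fold ranking computes thousands of such tests
  inside nested LOOCV). The effect size is the ϕ coefficient, signed so
  ϕ > 0 means the alteration is enriched among sensitive PDXs; numerically,
  ϕ equals the MCC formula applied to the 2×2 table.
* Real-valued features use Welch's unequal-variance t-test (a pooled-variance
  option exists). Degenerate features — no within-group variance — get p = 1
  and rank last; p-ties break by |effect| descending, then feature id, so
  rankings are reproducible and column-order invariant.
* Replicates: stochastic models run 10 LOOCV passes with a shared seed list;
  reported metrics are medians over non-NA replicates (all-NA stays NA).
  Model comparisons are paired t-tests on the matched replicate (or
  per-treatment) MCC vectors; all-zero differences return NA, and a
  numerically constant non-zero difference takes the zero-variance limit.
* A binary 0/1 predictor's ROC curve has a single intermediate point, so its
  AUC reduces to (TPR + 1 − FPR)/2; continuous scores sweep all distinct
  thresholds with trapezoidal area.

## The forest engine

Forests are fitted through two interchangeable, identically parameterised
backends: `randomForest` (the classical implementation, lowest call overhead
— used for feature subsets up to 64 columns under the default `"auto"`
policy) and `ranger` (used above that, where its tree construction scales
far better with feature count). Nested OMC runs fit tens of thousands of
tiny forests, so the crossover matters; either backend can be forced via
`rf_config(backend =)`, and the suite checks both discriminate a separable
fixture. All randomness flows from explicit seeds: one seed drives a whole
replicate (outer and inner loops alike), and identical (data, config, seed)
triples reproduce byte-identical outputs.

## The synthetic cohort generator

Real PDX workbooks are large downloads; the generator provides cohorts with
known ground truth so every pipeline stage is testable at the desk. Classes
are Bernoulli draws at the requested prevalence. Planted binary features are
parameterised by the alteration rate in the resistant class and the odds
ratio between classes (defaults 0.1 and 20); planted real-valued features by
a standardised mean shift (default 1.5) on a Gaussian around a positive
baseline, clamped at zero to respect the expression scale. Noise features
are class-independent. Volume curves come from piecewise-linear
category-typical trends (regression to −100% for CR, partial regression for
PR, near-flat for SD, rapid growth for PD) plus Gaussian noise, with
rejection sampling until the curve's statistics sit at least 5 percentage
points inside the target category's region — so categorisation round-trips
by construction.

The default cohort — 40 samples, prevalence 0.5, 3 planted SNV-like features
(odds ratio 20) among 500 noise features — is the regime in which
feature-selection recovery is expected and in which the acceptance checks
run: RF-OMC's nested MCC is high, its selected subsets recover planted
genes, and RF-all (diluted by 500 noise features) does worse. What the
generator does *not* emulate: co-mutation and co-expression structure,
mutational signatures, batch effects, or any relation between the profiles.
Passing recovery tests therefore show the selection machinery works where
univariate signal exists; they do not promise comparable MCCs on real
cohorts, where signal may be weaker, correlated or multivariate.

## Problem sizes and numerical choices

The test suite exercises the full nested pipeline at the cohort sizes above
with 100-tree forests and 10 replicate seeds for the recovery experiment,
and 30-sample / 300-feature cohorts with 50-tree forests for the
selection-bias control; unit tests use smaller fixtures with 20-tree
forests, leaning on the observation that forests over two or three features
are ensembles of near-duplicate shallow trees, so tree counts well below the
1000-tree default lose nothing. Degenerate situations are all defined, not
accidental: single-class training folds predict the training majority
(logged); single-class cases are flagged and produce all-NA results with a
reason; duplicate gene rows keep the row deviating most from the profile
median; profile tables round-trip at full floating-point precision.

## Limitations

Univariate ranking can miss purely cooperative feature sets (a pair
predictive only jointly); the permutation-importance ranking backend is
provided as an alternative but is never the default. The OMC grid never
considers exactly one feature (the single-gene model covers that
hypothesis). No multiple-testing correction is applied to ranking p-values —
they are ordering devices, not inference. Survival endpoints, dose
modelling, batch correction and multi-omics factor integration are out of
scope.
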