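---
title: "Predicting mouse TLR9 agonist activity of CpG ODNs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mouse TLR9 agonist activity of CpG ODNs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Toll-like receptor 9 (TLR9) recognizes single-stranded DNA
oligodeoxynucleotides (ODNs) carrying unmethylated CpG dinucleotides.
Synthetic CpG ODNs that activate mouse TLR9 (mTLR9) are candidate vaccine
adjuvants, but reporter-cell screening of candidate 24-mers is slow, and the
sequence space (4^24) is enormous. `odnscreen` builds a sequence-only
classifier of mTLR9 activity from a modest labelled training set and uses it
to rank unseen candidates, so that only a top slice need be synthesized and
assayed.

The training input is a table of ODN sequences with reporter-assay activity
scores (optical-density readout, observed range 0 to 1.14). Scores at or
above 0.4 define the high-activity class; below 0.4, the low class. Typical
data are strongly imbalanced toward the low class (roughly 2.5 low : 1
high), which drives most of the design below.

## Featurization

Four feature families are computed per sequence; all are cheap, exact
functions of the string.

**Nucleotide counts.** `A`, `T`, `G`, `C`. Characters outside the strict
alphabet are ignored in counting (ingestion, by contrast, rejects them:
sequence validation uppercases and then requires pure A/C/G/T).

**Motif counts and distances.** For each motif `m` in a configured list, the
occurrence count `n_m` (all overlapping matches) and three distance
descriptors built from the first three occurrence positions
`p1 < p2 < p3`:

\[
d_{m}2\_1 = p_2 - p_1 + n,\qquad
d_{m}3\_1 = p_3 - p_1 + n,\qquad
d_{m}3\_2 = p_3 - p_2 + n,
\]

where `n` is the number of nucleotides before the *latter* occurrence of the
pair, i.e. `p_latter - 1`. The `n` term anchors the pair inside the ODN: two
sequences whose CG pairs have the same gap but sit at different offsets get
different descriptor values (the two worked examples in the README evaluate
to 12 and 19 for an identical gap of 4). When the required occurrence is
absent the whole descriptor is 0; this is the only reading that keeps the
descriptors well-defined non-negative integers. Positions are 1-based —
the worked example "9 − 5 = 4" forces this convention.

The motif list itself is a modelling choice. Two options are provided:

* the fixed preset `default_distance_motifs()` = CG, AG, GG, CC, TCT, TTC,
  TGT — the published feature set;
* data-driven selection (`select_distance_motifs()`, the `ensemble_fit()`
  default): all position-free motifs of length 2–6 whose occurrence rate
  differs by at least 10 percentage points between the high and low groups
  of the *training* split. This reuses the same 10% occurrence-difference
  rule that defines the fingerprint dictionary, rather than introducing a
  second arbitrary constant, and deliberately tolerates redundancy among
  selected motifs (e.g. GG alongside GGC): pruning correlated features is
  the feature pipeline's job, not the selector's.

**Graph-derived rigid-body features.** The sequence is embedded as a 2D walk
of unit steps — A (0,+1), T (0,−1), G (+1,0), C (−1,0) — and each base
deposits a unit point mass at the walk position after its step. The feature
set is the center of mass (`Mu_x`, `Mu_y`), the principal moments of inertia
`PMI1 >= PMI2` (eigenvalues of the planar inertia tensor about the center of
mass) and the radius of gyration `Rg = sqrt((PMI1 + PMI2)/N)`. The
trace identity `Rg^2 * N = PMI1 + PMI2` holds exactly and is tested. The
four-direction unit-step mapping is this package's documented convention;
published 2D DNA embeddings differ in coordinate details, so absolute
PMI/Mu values are comparable only within one convention.

**Positional binary fingerprints.** Every substring of length 2–6 paired
with its 1-based start is a token (`"TCG"` yields TC@1, CG@2, TCG@1). A
token enters the dictionary when the fraction of ODNs containing it (once
per ODN, regardless of multiplicity) differs between the groups by at least
the threshold (default 0.10, inclusive). Fingerprint bit *i* of a sequence
is 1 iff dictionary token *i* occurs at exactly its stored start. Dictionary
order (descending rate difference, then motif, then start) fixes the bit
order for serialization.

Fingerprints also drive *deduplication*: near-identical ODNs inflate
apparent performance, so the low-activity group is thinned by greedy leader
clustering on Tanimoto similarity (default cutoff 0.85, first-seen record
kept). Tanimoto of two all-zero fingerprints is defined as 1: two ODNs the
dictionary cannot see at all are indistinguishable, and treating them as
identical is the conservative choice for deduplication.

## Feature pipeline

Fit on training data only, then applied frozen to test/screening data:

1. near-zero variance: drop columns with sample SD (n−1 denominator) below
   0.3;
2. linear combinations (binary fingerprint block): greedy forward pass with
   an implicit intercept, QR rank tolerance 1e-8, dropping later-ordered
   dependent columns — with the intercept, complementary bit columns are
   caught;
3. correlation (numeric block): while any pair has |Pearson r| > 0.85
   (strictly), remove the member of the worst pair with the larger mean
   absolute correlation, ties to the later column;
4. center and scale with training means/SDs.

The thresholds 0.3 and 0.85 are the reference method's values. Filters are
deterministic and order-stable; the test suite checks that permuting test
rows cannot change any fitted parameter (no leakage).

## Resampling and the ensemble

Each of `n_repeats = 20` repetitions: down-sample the majority class without
replacement to the minority size (seeded; the repeated-down-sampling reading
of "bootstrap test samples" follows the method's own description of the
procedure), stratified 80/20 split with per-class rounding to the nearest
integer (117 per class gives 94/23, totals 188/46), and stratified k-fold
assignment of the training set. Per-repeat seeds are `master + i`, so any
repeat is reproducible in isolation.

Each repeat trains one member: its own dictionary, motif list and pipeline
(fit on that repeat's training data; `global_dictionary = TRUE` instead fits one
global dictionary from all records, reproducing the simpler global protocol
at the cost of mild leakage), then a 500-tree random forest with `mtry`
tuned over {floor(sqrt(p)/2), floor(sqrt(p)), floor(2 sqrt(p))} by k-fold
cross-validated balanced accuracy (ties to the smaller `mtry`).

Consensus prediction: score = mean of member high-class probabilities
(majority vote available as an alternative), label high iff score >= 0.5
(a score exactly at the threshold is high, documented and tested), ranking
by descending score with ties broken by id so input order never matters.

Baseline families for benchmarking (`train_baseline()`): gradient-boosted
trees (xgboost), shrinkage discriminant analysis (linear discriminant with
the pooled covariance shrunk toward its diagonal — written in-package),
RBF-kernel SVM (e1071) and a single-hidden-layer neural network (nnet),
all under the identical CV protocol and predict-probability contract. These
are comparison plumbing; no claim of hyperparameter parity with any
published benchmark run is made.

## Metrics

Sensitivity, specificity, balanced accuracy, MCC and precision from the
confusion matrix with high as positive class. Zero-denominator metrics are
reported as `NA` and named in an `undefined` attribute instead of being
silently coerced. Percentages print to one decimal (half-away-from-zero)
and MCC to two, matching conventional reporting.

## Motif statistics

Separately from the positional fingerprints, position-free motif analysis:
per-motif occurrence percentages in the two groups and their absolute
difference (ranked), and the effect of motif presence on the activity score
within a group by a two-sided Mann–Whitney U test — exact when the smaller
subset has at most 8 observations and scores are tie-free, otherwise normal
approximation with tie and continuity correction (the two branches agree
within 0.02 in the tested small-sample range). Direction comes from the
median comparison; significance at p < 0.05. P values are reported raw, as
is conventional for this analysis; a Benjamini–Hochberg column is available
as an explicitly optional extra.

## Synthetic data generator

`simulate_odn_dataset()` draws i.i.d. uniform sequences (default 24-mers)
and assigns activity = clip(baseline + sum of effects of contained motifs +
Gaussian noise). Defaults: baseline 0.18 (the low-group median in the
reference data), effects GGC +0.35 (0.18 + 0.35 = 0.53, the high-group
median), CCCG +0.30, TCT −0.10, noise SD 0.05, clipping to [0, 1.14] (the
observed score range). At n = 400 this yields roughly 30% high-activity
ODNs, echoing the reference data's imbalance. The generator emulates the
*statistical* structure of reporter data — additive motif effects, bimodal
scores around the 0.4 cutoff, class imbalance — and none of its biochemistry
(no dose-response, no backbone chemistry, no position-specific effects, no
motif interactions). A pipeline that passes the synthetic benchmark is
therefore shown to recover planted containment signals through the full
train/test machinery without leakage; it is not thereby validated on real
assay data.

## Benchmark problem sizes and observed behavior

The packaged end-to-end benchmark uses n = 400 simulated ODNs, 20 ensemble
members, k = 5 cross-validation folds within members, 500 trees, and a
6000-candidate screening pool — sizes chosen to exercise every component at
the reference method's repeat count while keeping a full run in minutes on
one CPU. Under fixed seeds the suite verifies: mean held-out balanced
accuracy above 0.85; label-shuffled data at 0.5 ± 0.1 (null calibration);
all three planted motifs flagged by the Mann–Whitney analysis at p < 0.05
with the planted direction.

One property of the consensus deserves emphasis. The ensemble ranks by the
mean *class probability*, i.e. by certainty of exceeding the activity
cutoff, not by expected activity magnitude. Once a candidate contains a
clearly sufficient motif its score is near the ceiling, so among confident
positives the ranking carries little information about *how far* above the
cutoff a candidate sits. Consequently the top slice of a screen is close to
a uniform draw from the confident positives: motifs common among positives
appear at prevalence folds near the 1/prevalence ceiling, and rare strong
motifs are not preferentially concentrated. `screen_enrichment()` reports
per-motif prevalence folds (selection rate / pool rate) so this behavior is
visible; ranking by expected activity would require a regression model,
which is outside this package's scope.

## Degenerate inputs and numerical conventions

* Sequences shorter than a token's span simply yield 0 bits; sequences
  shorter than 2 produce an empty token set.
* Distance descriptors with missing occurrences are 0 by definition.
* `graph_features()` of a single point is all-zero inertia; empty point sets
  are an error.
* Ties in `mtry` tuning go to the smaller value; ties in ranking go to the
  lexicographically smaller id; the correlation filter breaks mean-|r| ties
  toward the later column.
* All randomness flows through `withr::with_seed`, so no call disturbs the
  caller's RNG and every artifact is reproducible from the master seed.

## Known limitations

* Sequences are treated as unmodified A/C/G/T; phosphorothioate backbones
  and other chemical modifications common in therapeutic ODNs are invisible
  to the featurization.
* The 2D-walk convention is package-specific (see above); graph feature
  values are not transferable across conventions.
* The dictionary, motif selection and pipelines are refit per ensemble
  member; with very small training sets the dictionary can be empty, in
  which case classification rests on the numeric block alone.
* Class-probability ranking saturates for confident positives (see the
  benchmark section); magnitude-aware ranking is out of scope.
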