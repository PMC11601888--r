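---
title: "Methods: multi-omic functional lncRNA prediction with funlnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic functional lncRNA prediction with funlnc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funlnc)
```

## The problem and the model

Functional lncRNAs — those that measurably influence a cellular phenotype
such as stem-cell self-renewal or cancer cell growth — are rare, and the
experiments that identify them (CRISPRi screens, knockdowns) are
expensive. The premise of this package is that function leaves a
regulatory footprint: functional lncRNAs tend to sit in promoters densely
occupied by transcription factors and activating histone marks, contact
enhancers and super-enhancers through 3D chromatin loops, and engage more
downstream partners. `funlnc` turns that footprint into a supervised
classification problem:

1. **Network assembly.** Interval-level (epi)genomic evidence is attached
   to each lncRNA promoter as typed, provenance-carrying edges.
2. **Featurization.** The neighborhood of each lncRNA is summarized into
   57 numeric features in three categories (proximal, distal,
   downstream).
3. **Classification.** A random forest is trained on labeled functional /
   nonfunctional lncRNAs and applied genome-wide.
4. **Prioritization.** An empirical permutation score separates
   high-confidence functional calls from the merely-above-threshold.

## Coordinates and assignment rules

All files are read with BED semantics (0-based, half-open); intervals are
carried internally as `GRanges` and converted on load, so an element
ending at position x never touches a promoter starting at x. Three
assignment manners create upstream edges:

* **proximal** — element overlaps the promoter window. The promoter is
  TSS ± `window`; the default `window = 2000` is the common promoter
  convention. It is configurable because no single window is canonical;
  the choice trades proximal-feature sensitivity against specificity and
  the default behaves well across the simulated worlds below.
* **distance_assigned** — enhancer/SE/accessibility calls (ROSE-style
  output, consumed as input; a naive stitcher `stitch_enhancers()` is
  provided only as a convenience) whose midpoint lies within `max_dist`
  of the TSS, defaulting to 50 kb, the usual enhancer-to-gene assignment
  radius. A call overlapping the promoter is linked regardless of
  distance.
* **chromatin_interaction** — the element overlaps one anchor of a BEDPE
  pair and the promoter overlaps the other. A link supported by several
  pairs collapses to a single edge carrying the *sum* of the pair
  frequencies: edge lists stay unique while the 3D-frequency feature
  remains additive. Both manners are computed in parallel for every
  distal kind, as the feature schema requires.

Expression-correlation edges are deliberately out of scope: they would
require expression matrices and a correlation threshold that the method
does not otherwise need, and none of the 57 features consumes them.

## The 57-feature schema

The category structure is fixed: C1 = 8 proximal features, C2 = 46 distal
features (super-enhancer 12, typical enhancer 23, accessibility 10, 3D
frequency 1), C3 = 3 downstream features. Within C2 the published
material fixes only these cardinalities, not the identity of every
column, so the schema pins a documented stand-in that reproduces them
exactly:

* SE: 2 manners × {count, signal_sum, signal_max, rank_mean, rank_best,
  constituent_count} = 12
* TE: 2 manners × {count, signal_sum, signal_max, signal_mean, rank_mean,
  rank_best, constituent_count, prom_overlap_count, nearest_dist_norm,
  freq_weighted_count, sample_count} + 1 combined TE∪SE count = 23
* Accessibility: 2 manners × {count, signal_sum, signal_max, rank_mean,
  rank_best} = 10

Every statistic is well defined and individually tested; the schema is a
first-class object (`feature_schema()`), validated before any
computation, and swappable should the authoritative per-column list
become available.

Distinctness rules matter: TF counts are counts of distinct TF
*identities* (the per-TF indicator is 0/1, so two biosamples or peaks of
SOX2 count once), whereas `constituent_count` counts peaks and
`sample_count` counts biosamples — this is why edges carry `sample_id`.

**Normalization.** "Normalized signal" and "normalized rank" are
cohort-relative because no fixed constants are published: the methylation
signal is divided by the maximum per-lncRNA sum in the analyzed set, and
the rank of an element with descending-signal rank r in a pool of M is
(M − r + 1)/M ∈ (0, 1] — higher signal maps nearer 1, matching the use of
signal strength as activity evidence. Ranks are invariant to positive
rescaling of all signals (tested). lncRNAs with no linked elements get 0
everywhere; the matrix never contains missing values.

## Classifier

Preprocessing standardizes each feature by its training-set mean/SD,
drops zero-variance columns, and screens correlated pairs (|r| > 0.95,
dropping the member with the larger mean absolute correlation) — the
conventional reading of "standardized and screened predictors"; test data
only ever see training statistics. The forest itself is implemented
in-package (Rcpp): bagged CART trees grown to purity with Gini splitting,
`mtry` candidate features per split tuned over {√p/2, √p, 2√p} by
stratified 10-fold cross-validation maximizing AUROC, 500 trees by
default. Probabilities are across-tree means of leaf class fractions, and
the whole fit is exactly reproducible from its seed (the forest RNG is
self-contained). Mean-decrease-Gini importances are accumulated during
training. The environment provides no random-forest package, and the
forest is the analytical core of the method, so implementing it (rather
than approximating with a different learner) was the only faithful
option; the exact tuning grid of the original caret workflow is not
reproduced.

Two split protocols are provided. The random split is stratified 80/20.
The grouped split first clusters sequences by single-linkage over k-mer
Jaccard similarity (k = 8, threshold 0.3 — k-mer sets are a cheap,
deterministic stand-in for an MMseqs2-style clustering) and then assigns
whole clusters greedily, largest first, to whichever side is furthest
below its target size. Leakage is identically zero by construction; when
a giant cluster forces the achieved fraction away from the target, the
function warns rather than splitting the cluster.

Evaluation uses the midrank (Wilcoxon) AUROC and step-integrated AUPRC.
Labels use the ≥-threshold convention: a probability exactly at the
threshold (default 0.5) counts as functional.

**Noise robustness.** The published robustness experiment "adds noise" at
5/10/15% without specifying whether labels or features are perturbed;
label flips were chosen because they are well defined, reproduce the
graceful-degradation pattern, and keep the feature distributions intact.
Exactly ⌊rate·n⌋ labels are flipped per iteration and the flipped ids are
recorded for audit.

**Feature contribution.** Odds ratios and relative risks dichotomize each
feature at its median against the predicted label, with the Haldane
(+0.5) correction whenever a 2×2 cell is empty.

## Random permutation score

Columns of the feature matrix are permuted independently across rows —
the displayed scrambled matrix is ambiguous between joint and per-column
shuffling, but only per-column shuffling preserves every feature's
marginal distribution, which the null requires. Ties `p_i = r_ik` do not
count as exceedances (the indicator is strict). Two estimators are
offered because the raw formula is undefined at c = 0: `raw` is
−log10(c/B), exactly the published formula (+∞ at c = 0, and at B = 1000
the ">2" high-confidence rule is precisely c ≤ 9); `safe`, the default,
is −log10((c+1)/(B+1)), the add-one empirical p-value, finite and capped
at −log10(1/(B+1)) ≈ 3.0004 for B = 1000. Under the null the exceedance
fractions are approximately Uniform(0,1) (KS-tested). A lncRNA is flagged
high-confidence iff its score strictly exceeds 2 *and* it was labeled
functional.

## The simulated world

The generator exists so every stage is testable without downloads. Its
defaults state the world once: 200 lncRNAs, 60% positive (mirroring the
238:152 ratio of the curated hESC positive/negative sets), promoters on a
~500 kb grid over two 50 Mb chromosomes (far enough apart that distal
assignment never crosses genes), per-promoter element counts
Poisson(λ_class) with λ_pos = 8 vs λ_neg = 2 on the informative kinds (TF
ChIP, histone marks, typical enhancers) and class-balanced rates
elsewhere, log-normal signals (meanlog 1.5 vs 1.0 on informative kinds,
sdlog 0.5), 70% of distal elements wired to their promoter by an anchor
pair with frequency 1 + Poisson(2), downstream degrees Poisson with
pos/neg rates 5/1 (mRNA), 3/1 (miRNA), 2/1 (protein), and near-duplicate
sequence clusters for grouped-split tests. Poisson counts plus log-normal
signals are the minimal model reproducing the reported class separation
("functional lncRNAs are higher on most features"); none of these values
were adjusted after observing test outcomes.

What a green test does establish: the pipeline recovers planted class
structure essentially perfectly (held-out AUROC ≥ 0.95), degrades
monotonically under label noise, collapses to chance when the world is
flat or labels are permuted, and loses ≥ 0.2 AUROC when the only
informative category is ablated. What it does not establish: performance
on real (epi)genomic data, whose feature correlations, genomic clustering
and label noise are richer than this generator; the published headline
metrics depend on thousands of external datasets and are not reproducible
at desk scale.

## Numerical choices and degenerate inputs

* Empty element files, lncRNAs without edges, and empty pair tables are
  valid inputs yielding zero-features, never errors.
* A single-row matrix permutes to itself; `B = 0` is rejected.
* Split thresholds in the forest are midpoints of adjacent sorted values;
  all text serialization of models and features uses `%.17g`, so a
  written-and-reloaded model reproduces probabilities bit for bit.
* `train_frac = 1` produces an empty test set with a warning rather than
  an error (legitimate when fitting a final model).
* Seeds: every stochastic function takes an explicit seed; derived
  sub-seeds keep stages independent. Global RNG state is saved and
  restored around every seeded operation.

## Known limitations

* The C2 stand-in schema matches the published cardinalities but not
  necessarily the original per-column definitions.
* Expression-correlation edges and the alternative-learner comparison are
  not implemented (out of scope).
* The grouped split optimizes the global 80/20 target, not per-class
  balance within the split; with few, large clusters the positive rate of
  the test set can drift.
* The k-mer Jaccard clustering is a simple surrogate for
  alignment-based sequence clustering and will under-link distant
  homologs.
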