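---
title: "Methods: consensus forest classification of oral bioavailability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus forest classification of oral bioavailability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hobclass)
```

This vignette is the package's own account of the model it implements, the
choices made where the design was genuinely open, and what the test suite
does and does not establish about real data.

## The classification model

Human oral bioavailability (%F) is measured on a 0–100% scale, and the
field dichotomizes it at a cutoff — 20% and 50% are the two conventions the
package defaults support, though any cutoff in (0, 100) works. Measured
values are often imprecise, so `hobclass` stores every %F value as an
interval `[lo, hi]` (a point value has `lo == hi`) and labels at cutoff *c*
by interval position:

* positive iff `lo >= c` (a point value equal to the cutoff is positive);
* negative iff `hi < c`;
* **discarded** otherwise — the interval straddles the cutoff, so the class
  is genuinely undetermined.

Discarding is a flag, not a deletion: the records stay in the dataset so
per-class accounting always partitions the input. This interval rule is the
deterministic operationalization of the common practice of dropping
molecules whose measurements cannot support a class at a stricter cutoff;
it reproduces the characteristic shrinkage of datasets when moving from a
50% to a 20% cutoff. Two properties follow and are tested: relabeling at
the same cutoff is a no-op, and lowering the cutoff never loses positives.

## Curation

Test chemistry must not leak into training chemistry. Deduplication runs in
two stages: (1) canonical SMILES equality after keeping only the largest
fragment (standard salt/mixture handling in QSAR curation — the backend's
canonical form decides identity, so stereochemistry-aware resolution is out
of scope); (2) exact topological path-fingerprint identity, i.e. Tanimoto
similarity 1.0 against any reference molecule. Stage 2 is deliberately
conservative: hashed fingerprints can collide (two alkane homologs longer
than the hashed path length share every path), and a collision removes the
molecule rather than keeping a near-duplicate. For the same reason the
Tanimoto of two all-zero fingerprints is defined as 1 (and logged).
Fingerprint identity at exactly 1.0, rather than a looser threshold, is the
package's fixed choice for the second stage.

The train/test proximity audit reports each query molecule's maximum
Tanimoto similarity over the reference set and the mean of those maxima.
The absolute numbers depend on the fingerprint dialect — here the
backend's 1024-bit hashed linear-path fingerprint — so they are comparable
within one pipeline, not across engines.

## Descriptors

Descriptor engines are injected through a provider contract: a function
from one SMILES string to a named numeric vector. The default provider
computes a small interpretable 2D set (molecular weight, logP, topological
polar surface area, molar refractivity, H-bond donor/acceptor counts,
fluorine, atom and bond counts) through the OpenBabel backend; a larger
engine can be swapped in without touching the rest of the pipeline, and the
tests inject tiny deterministic providers. Provider failures on individual
molecules become non-finite rows (visible, warnable), not silent drops.

Filtering removes three kinds of degenerate columns — all-zero, constant,
and any-non-finite — with a per-column reason, and is idempotent: surviving
columns have at least two distinct finite values. No scaling is applied
before forest training (trees are scale-invariant); standardization happens
only inside the PCA domain model.

## The consensus ensemble

The training data are split once into `n_folds = 5` stratified folds under
the configuration seed; member *i* is a random forest fitted on the four
folds other than *i*. This is the reading of "five models from fivefold
cross-validation" in which each member is a fold-complement model, so the
five held-out folds provide leakage-free training-set performance numbers.
The same split serves both hyperparameter selection and member definition;
an independent split for tuning would be a defensible alternative, at the
cost of a second stratification.

Only two hyperparameters are tuned — the number of trees and the minimum
leaf size — by mean accuracy over the five folds on a grid whose defaults
(`n_estimators` in {10, 31, 50, 100, 200}, `min_samples_leaf` in
{1, 2, 4, 6, 8}) bracket the optima conventionally reported for this
problem (31/6 at the 50% cutoff, 10/6 at 20%). Restricting the search this
way limits overfitting; everything else stays at the learner's defaults.
Ties resolve to the smaller tree count, then the smaller leaf size, making
the search fully deterministic.

Prediction: each member votes the class given by the majority of its trees
(a tied tree vote — possible with an even tree count — resolves to
negative, the conservative call for a bioavailability screen). The
consensus label is the equal-weight majority of the five member votes
(five members cannot tie), and the consensus score is the mean of the
members' positive-class probabilities — the only continuous score
consistent with equal voting weights — used for the consensus ROC/AUC.
Unanimous rows can never be overturned by voting; this is asserted as an
invariant.

Every source of randomness (fold assignment, each forest fit, each grid
point's fits) is derived from the configuration seed, so
(data, config, seed) determines fold assignments and predictions exactly.
The retraining-stability protocol re-splits an enlarged pool (training plus
an extra labeled set) with a fresh seed per round, retrains the full
ensemble, and reports the mean and standard deviation of consensus
accuracy on a fixed evaluation set over the rounds.

## Evaluation metrics

Sensitivity, specificity, accuracy and F1 follow their standard
definitions. For the Matthews correlation coefficient the package uses the
standard denominator √((TP+FP)(TP+FN)(TN+FP)(TN+FN)); a variant sometimes
seen in print that repeats (TP+FN) and omits (TP+FP) is not the Matthews
coefficient (it breaks MCC = 1 for perfect prediction on unbalanced data)
and is treated as a typographical artifact. Any metric with a zero
denominator is defined as 0 and flagged in the report rather than returned
as NaN.

The ROC curve sweeps all score thresholds; the trapezoidal AUC then equals
the Mann–Whitney probability that a random positive outscores a random
negative with ties counted 1/2. The tests verify this identity against an
explicit pair-count oracle and against an independent ROC implementation,
and check invariance under strictly monotone score transforms.

Ensemble diversity uses Yule's Q on the joint correct/incorrect counts of
two classifiers; Q is 0 when the cross-products tie (the independence
point), and the zero-denominator case — e.g. two identical *perfect*
classifiers, where no disagreement cell is populated — is also defined as
0. Tree-level diversity evaluates every unordered pair of trees in a
member on the full supplied matrix against the true labels (out-of-bag
restriction would be an alternative; the full-matrix choice makes the
statistic a property of the fitted trees, not of the bootstrap bookkeeping).

## Tree-path Shapley attributions

Attributions explain each member's positive-class probability. A forest's
probability is the mean of its trees' 0/1 leaf votes, so exact per-tree
Shapley values (with respect to the cover-weighted conditional expectation
the tree defines) average into exact forest attributions. The package
implements the polynomial-time path algorithm in C++: it walks each tree
once per explained molecule, maintaining for every unique feature on the
path the fraction of feature subsets flowing down with the feature included
or excluded, together with permutation weights for all subset sizes; the
unwound weights at a leaf yield each feature's exact Shapley value.

Node covers are computed by routing a background matrix through the tree.
For ensemble members the background is the member's own training folds,
which guarantees every split node has positive cover on both sides. A
branch that no background row reaches has probability zero under the cover
distribution and is pruned rather than divided by; this keeps arbitrary
user-supplied backgrounds well defined. Local accuracy —
`base_value + sum(phi)` equals the member's predicted probability — holds
to machine precision and is asserted at 1e-6 throughout the tests; the
implementation is additionally verified against an exhaustive
subset-enumeration Shapley oracle on small trees.

Consensus importance averages the per-member importance vectors (mean |φ|
per feature over the explained molecules), i.e. members are averaged after
taking importances, not pooled at the φ level. Averaging |φ| rather than
signed φ is the standard importance reading; signed averaging would
conflate direction with magnitude and can cancel a feature that matters in
opposite directions for different members. Occurrence counts tally, per
feature, how many members place it in their own top-k (k = 20 by default).
Dependence data pair feature values with mean φ across members and call
the direction by Spearman rank correlation, reported as indeterminate below
|rho| = 0.1.

## Applicability domain

Descriptors are standardized to zero mean and unit variance (their raw
scales differ by orders of magnitude) and projected on the two leading
principal components. A new molecule is inside the domain iff its
projection lies in the convex hull of the training projections, boundary
inclusive — the tightest convex reading of "within the range of the
training molecules"; an axis-aligned bounding box is available behind
`method = "bbox"` as a looser alternative. Membership is invariant to the
sign indeterminacy of principal axes, and the hull is determined by its
extreme points alone, so removing interior training points from the hull
construction changes no call. Numerically, the half-plane tests use a
tolerance of 1e-9 relative to the hull extent so that hull vertices
themselves always classify inside. Note that refitting the PCA after
removing a training molecule shifts the standardization slightly, so the
extreme-point property is a statement about the hull given a fixed
projection, and is tested as such.

## The synthetic generator and what passing tests mean

`generate_table()` draws i.i.d. standard-normal descriptor columns, labels
by a threshold on a linear combination of designated signal features, flips
each label independently with probability `flip_noise < 0.5`, and
optionally appends a constant and an all-zero column to exercise the
filter. The generator's defaults — 1000 molecules, 50 descriptors, one
signal feature, 10% flips — are the study conditions used by the recovery
tests and the acceptance script: they give a Bayes accuracy of 0.9, a
realistic ceiling for a QSAR classification task of this size, with a clear
planted ground truth for both accuracy and importance recovery. Attribution
recovery is measured on a 200-molecule subset of the training matrix, which
is ample for ranking a single dominant signal.

What the generator does *not* emulate: real descriptor marginals (heavy
tails, counts, bounded ranges), inter-descriptor correlation structure, and
any relationship between chemistry and label beyond the planted rule.
Passing recovery tests therefore demonstrates that the pipeline's machinery
— splitting, voting, scoring, attribution, domain geometry — is correct,
not that a particular descriptor engine predicts real bioavailability.
Published headline accuracies on deposited datasets depend on the original
descriptor engine and its version; reproducing them requires injecting
that engine through the provider contract and supplying the deposited
tables, which is deliberately outside the offline test surface. The
separate SMILES fixture set (20 hand-curated molecules with fabricated %F
values spanning both cutoffs, one boundary point value and two intervals)
exercises the chemistry-facing paths end to end.

## Numerical and degenerate-input conventions

* Tuning ties → smaller `n_estimators`, then smaller `min_samples_leaf`.
* Member tree-vote tie → negative; five-member consensus cannot tie.
* Tanimoto of two empty fingerprints → 1 (logged); metric or Q
  denominators of zero → 0 (flagged).
* Zero-cover tree branches under the attribution background → pruned.
* Stratification requires each class to fill every fold; violations raise
  an actionable error rather than silently merging folds.
* Labels must be binary 0/1; single-class inputs error in tuning, ROC and
  fold construction.
* The PCA domain requires ≥ 3 molecules, no constant columns (filter
  first) and rank ≥ 2; degenerate hulls (< 3 distinct vertices) fall back
  to a bounding box.

## Known limitations

* The default descriptor provider is a compact property set, not a
  1000+-descriptor engine; it is meant as a working default and a contract
  exemplar.
* Canonical-form deduplication does not resolve stereoisomers beyond what
  the canonicalizer encodes.
* The applicability domain is a 2D convex region; leverage- or
  distance-based domains are out of scope.
* Attribution backgrounds other than the member's training folds are
  supported but change the baseline; covers are always recomputed from the
  supplied background.
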