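---
title: "Ranking compounds by multi-target activity profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking compounds by multi-target activity profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multirank)
```

## The problem

In multi-target drug design a lead candidate should show a *profile* of
activities — active on one or several main targets, ideally inactive on
targets to be avoided. High-throughput screens against several targets on
the same library yield, for each compound $i$, a binary activity profile
$(y_{i1}, \dots, y_{im})$ with $y_{ik} \in \{0, 1\}$. Perfectly matching
ligands are rare, so a useful screening model should not merely classify:
it should *rank* the library so that exact-profile compounds come first,
compounds that almost match the profile come next (they are starting
points a chemist can optimize), and decoys come last.

`multirank` implements this as a learning-to-rank problem: the
multi-target labels are collapsed into one integer rank score per
compound, and a linear large-margin ranking function
$f(\mathbf{x}) = \mathbf{w}^\top\mathbf{x}$ is trained on sparse molecular
fingerprints so that the induced ordering reproduces the scores.

## Rank-score encodings

`build_scheme()` constructs a total map from all $2^m$ profiles to integer
scores. The desired profile (active on every main target, inactive
elsewhere) gets the unique maximum; the all-inactive profile always gets
0. Between the two, profiles are screened by hard decoy rules and then
graded by their deviation:

* **Decoy rules** (score 0): inactive on every main target; active on an
  undesired target while also missing a main target; and, when
  `nonselective_as_decoy = TRUE`, active on all $m$ targets.
* **Grading** of the survivors: sort by (number of undesired activities,
  number of missed main targets), refined by the user's priorities —
  an activity on a higher-priority avoid target, or a miss of a
  higher-priority main target, counts as more severe. Profiles with equal
  severity share a score, and scores form the contiguous range
  `0..max`.

For three targets the four standard parameterizations (single or dual
main targets, equal or ordered priorities, with or without non-selective
decoys) are reproduced cell for cell; the construction extends unchanged
to any $m$. For $m > 3$ the relative order of *mixed* deviations is not
externally defined; our rule (any undesired activity is more severe than
any single main-target miss, which the dual-target table fixes for
$m = 3$) is a documented generalization, not a claim about what other
implementations would do.

Two simpler labelings are provided for comparison: `binary_labels()`
(active on all main targets vs. not) and `srank_encode()`, the
three-level selectivity labeling that puts selective compounds at 1,
decoys at 0 and non-selective actives at $-1$. The latter deliberately
ranks non-selective actives *below* decoys; the rank-score encodings
instead keep them above decoys on the grounds that their fingerprints
still carry target-relevant information, and the two conventions can be
compared directly in the harness. Compounds active on all targets can
optionally be removed beforehand (`filter_promiscuous()`,
`drop_promiscuous` in the harness) when such breadth is suspected to be
assay noise rather than pharmacology; the default keeps them.

## The ranking model

Training data are pairs $(\mathbf{x}_i, s_i)$. The ordered pair set
$P = \{(i, j) \mid s_i > s_j\}$ defines the pairwise ranking error

$$ \mathrm{err}_{\mathrm{rank}} = \frac{1}{|P|} \sum_{(i,j) \in P}
   \Big[ \mathbf{1}_{f(\mathbf{x}_i) < f(\mathbf{x}_j)} + \tfrac12\,
   \mathbf{1}_{f(\mathbf{x}_i) = f(\mathbf{x}_j)} \Big], $$

which on binary scores equals $1 - \mathrm{AUC}$. Because a swap between
score 3 and score 0 is worse than one between 2 and 1, evaluation and
training use the *k-partite* error, which weights each pair by
$s_i - s_j$ and normalizes by the total weight
$W = \sum_P (s_i - s_j)$ (`kpartite_error()`).

The trained objective is a convex surrogate. Two variants are available
in `train_config()`:

* **margin rescaling** (default): each pair must be separated by a margin
  equal to its score difference,
  $J(\mathbf{w}) = \tfrac12\lVert\mathbf{w}\rVert^2 + \frac{C}{W} \sum_P
  \max\{0,\, (s_i - s_j) - \mathbf{w}^\top(\mathbf{x}_i -
  \mathbf{x}_j)\}$;
* **slack rescaling**: a unit margin whose violation is multiplied by the
  score difference.

Both are upper bounds on the (scaled) k-partite error; margin rescaling
is the default because it most directly expresses "distant scores demand
wide separation". There is no intercept — rankings are invariant to
additive constants. Dividing the loss by $W$ keeps the two terms on
comparable scales across data set sizes.

**C semantics.** The cross-validation grids used by the harness
($10^{-6}..10^{-2}$ for the ranking methods, $0.1..1000$ for the
classification methods) are quoted in *per-pair* (summed-slack) units,
the convention of the linear SVM libraries such grids are usually tuned
for. Since the objective above normalizes by $W$, the harness multiplies
a grid value by $W$ of the training scores before fitting. Without this
conversion every grid value lands in the same vanishing-regularization
limit (the cross-validated error profile is flat and the model direction
degenerates to a difference of group means).

## Solver and complexity

`fit_ranksvm()` minimizes the objective by dual coordinate descent over
the ordered pairs, with a private deterministic shuffling stream (models
are reproducible from `(data, config, seed)` across platforms). After
each pass the duality gap is evaluated; the solver stops when
$\mathrm{gap} \le \mathrm{tol}\cdot\max(1, |J|)$, which *certifies* that
the returned objective is within `tol` (relative) of the optimum. If the
pass budget runs out first, the best iterate is returned with
`converged = FALSE` in the diagnostics and a warning. The SVC and the
Crammer–Singer multi-class SVM use the same machinery (per-instance
subproblems for the latter), so all three carry the same optimality
certificate; tests check each against an independent quadratic-program
solution of the fully expanded problem.

Evaluating the loss never requires materializing $P$:
`fast_weighted_loss()` sorts the $l$ predictions per score group once and
sweeps each of the $R(R-1)/2$ ordered group pairs with a merge pass,
giving $O(dl + R^2 l + l\log l)$ for $R$ distinct scores and average
sparsity $d$, and agrees with the brute-force $O(l^2)$ expansion to
$10^{-9}$ relative. The same sweep underlies `rank_error()` /
`kpartite_error()`, so test sets with thousands of compounds are cheap.
Tied predictions use *exact* floating-point equality, matching the metric
definition; a tolerance-based tie diagnostic is deliberately not part of
the metric.

## Molecular encoding

`ecfp()` produces hashed circular fingerprints: atom codes start from a
hash of (element, heavy degree, H count, formal charge, ring flag) and
are iteratively re-hashed with sorted (bond order, neighbor code) pairs
for `bond_diameter / 2` rounds (default diameter 6); codes from all
rounds are folded modulo `dim` (default $2^{20}$). The hash is our own
deterministic 32-bit FNV-1a: reproducibility within this package is what
the tests rely on, and downstream linear models depend on the fingerprint
*family*, not on any specific published bit assignment. Structural
deduplication of equivalent environments across rounds is not performed —
under binary folding a duplicate collides onto the same bit anyway.
Fingerprints are binary by default; a count mode exists but is secondary.
`cosine_normalize()` scales each fingerprint to unit norm so the sparse
dot product equals the cosine kernel and lies in $[0,1]$, removing the
molecule-size dependence of the raw dot product.

Structure input goes through OpenBabel/ChemmineR with explicit-hydrogen
expansion; `normalize_structure()` then keeps the largest fragment, folds
explicit hydrogens into per-atom counts, aromatizes simple (benzene-like
alternating or pre-flagged) rings, and renumbers atoms canonically via
invariant refinement with greedy individualization. This is deliberately
minimal preparation: neutralization, tautomer canonicalization and
coordinate cleaning are out of scope, and results on salt-stripped,
aromatized graphs are what the package's fingerprints are defined on.
Equal-size fragment ties are broken toward the lexicographically smallest
canonical signature and reported.

## Comparison methods

* `fit_svc()` — soft-margin linear SVC (L1 hinge, no intercept).
* `combine_models()` — per-target SVC weight vectors combined as
  $\mathbf{w}_{\mathrm{comb}} = \sum_k c_k \mathbf{w}_k$; the default
  factors are $+2$ for each main target and $-1$ for each undesired
  target, with alternatives (e.g. $+3/-2/-1$) available through
  `lc_factors`. Per-target models are labeled by activity on that target
  (actives vs. everything else, decoys included); the alternative of
  restricting positives to exact-profile compounds only is a stricter
  reading that we did not adopt, since each combined model is meant to
  capture one target's activity.
* `fit_mcsvm()` — Crammer–Singer multi-class SVM treating every rank
  score as a class, trained as one joint problem. Its prediction is a
  class, not a gradual ranking; `rank_by_mc()` therefore feeds the
  predicted class values (heavily tied) into the ranking metrics, where
  ties pay the $\tfrac12$ penalty. Exact argmax ties resolve to the
  lowest class value — measure-zero on real data, fixed for determinism.

## Experiment harness

`run_experiment()` reproduces the screening protocol: compounds are
grouped by profile; for each category (single-, dual-, triple-target) `n`
= half the smallest subset of that category is drawn from *each* subset
of the category; 1000 decoys (default; the whole pool with a warning if
smaller) are added; C is selected per method by stratified k-fold
cross-validation (default 2-fold) over the method's grid, ranking methods
scored by validation k-partite error, the SVC by binary rank error, ties
toward smaller C; the remaining compounds form the test set, labeled both
binary (main-target activity) and graded (the training scheme). All
methods of one repetition share the same split, so comparisons are
paired, and everything derives from one master seed. Folds are stratified
by score level because with two folds a rare level would otherwise
frequently vanish from one side; a split failing to cover every level is
re-drawn up to 10 times before failing loudly. `cutoff_sweep()` re-runs
the protocol over a list of pK$_i$ cutoffs (binarization is inclusive:
value $\ge$ cutoff is active) with stratified half-splits that preserve
the label distribution on both sides.

## The synthetic benchmark

`synthetic_spec()` / `make_benchmark()` generate populations with known
ground truth. Each target owns a disjoint block of "pharmacophore"
features; a compound active on a target carries each block feature with
probability `activation_prob`, and every feature is then flipped with
probability `background_noise` (XOR — noise can both add spurious bits
and erase signal). The default design is a three-target collection of
800 compounds — 90 per single-target profile, 60 per dual, 50 triple
actives, 300 decoys — with `activation_prob = 0.9`, ~20 background bits
per compound in a $2^{12}$ hash space, and 25-feature blocks: large
enough that every profile subset survives the half-split sampling rule,
noisy enough that errors are non-trivial, and small enough that
brute-force oracles stay cheap (production fingerprints use $2^{20}$;
nothing in the methods depends on the smaller test dimension). Feature
blocks are disjoint by default so that planted per-target models are
exactly recoverable; correlated targets can be emulated by supplying
overlapping blocks explicitly.

The generator emulates the *feature structure* the linear methods
assume — sparse additive per-target signal — and none of real chemistry:
no property-matched decoys, no scaffold clustering, no activity cliffs,
no assay noise structure. Passing tests therefore certify the
implementation (encodings, losses, solvers, protocol) and the relative
behavior of the methods under planted linear signal; they do not predict
absolute screening performance on real libraries.

Two benchmark regimes anchor the validation suite. In the noise-free
limit (`activation_prob = 1`, `background_noise = 0`) the score groups
are linearly separable by construction and the trained ranker must reach
k-partite error 0 on both the training and the held-out half. Under the
default moderate noise, a 20-repetition paired experiment (with 200
training decoys against the 300-decoy pool, a scaled-down stand-in for
the 1000-decoy protocol) checks the package's central comparative claim:
the graded ranking method attains lower test k-partite error than both
the linear combination and the multi-class SVM in the large majority of
repetitions.

## Numerical choices and limitations

* Duality-gap tolerances: `1e-6` for direct fits, `1e-5` inside the
  harness (ordering metrics are insensitive well before that).
* The hinge boundary (`margin` exactly met) contributes zero loss and
  zero subgradient; sweeps use strict inequalities consistently.
* Seeds: harness repetitions draw sub-seeds from one master seed; the
  solvers use a private xorshift stream, so results are bit-reproducible
  across platforms and never perturb the caller's RNG state.
* Problem sizes in the test suite (l of a few hundred, dim $2^{12}$,
  50-instance solver-vs-QP sweeps) are the package's own choice of
  smallest sizes at which every contract is still exercised.
* Canonical atom ordering uses hash-based refinement; two
  non-equivalent atoms colliding in the 32-bit hash could in principle
  break order invariance (probability $\sim 2^{-32}$ per comparison).
  Aromaticity covers simple rings only.
* Known limitations: linear models only (no kernels), binary activity
  labels (graded pK$_i$ scores enter only through cutoffs), no
  missing-label handling, and encodings are hard class maps — confidence
  or assay-quality weighting is out of scope.
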