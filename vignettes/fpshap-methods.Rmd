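---
title: "Methods: exact Shapley value analysis of fingerprint classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact Shapley value analysis of fingerprint classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpshap)
```

## The problem

Random forests (RF) and support vector machines with the Tanimoto kernel
(SVM) are the workhorse binary classifiers for activity-based compound
classification on binary molecular fingerprints. The two often produce
nearly indistinguishable predictions, which raises the question whether
they also *learn* the same thing. `fpshap` answers this by explaining both
model families with **exact Shapley values** — covering features that are
*present* (bit = 1) and *absent* (bit = 0) in a test compound — and by
aggregating those attributions into comparable statistics: instance- and
feature-based cumulative Shapley values, a feature contribution score,
correlations with model performance, prediction-pattern and
feature-contribution-pattern taxonomies, and an atom-level projection.

Because the full published benchmark rests on a large curated database
extraction, the package ships a synthetic fingerprint generator with
*planted* class structure instead: every downstream stage can then be
validated against a known ground truth, on a desk-scale budget.

## The synthetic world

`synthetic_pair_spec()` describes two compound classes of binary
fingerprints of length $m$:

* each class owns a disjoint set of *planted* bits, switched on with
  probability `p_planted_on` (default 0.9) in its own class and
  `p_cross_on` (default 0.05) in the other;
* all other bits are shared background, on with probability
  `p_background` (default 0.1);
* every bit is finally flipped independently with probability
  `noise_rate`.

The defaults put the two classes clearly apart in Tanimoto space while
keeping intra- and inter-class similarities in a realistic range; raising
`p_cross_on` toward `p_planted_on` shrinks the intra/inter similarity gap
monotonically (tested). `noise_rate` has no stated reference value; 0.01
(one bit error per 100 positions) was fixed once as a realistic
fingerprint-noise level and is not tuned anywhere. Generated compounds
carry clean potency annotations (pPot uniform in (5.5, 9.5), confidence
9, mass uniform in (250, 1000) Da) so they pass the curation filters;
`generate_activity_records()` manufactures records violating exactly one
labelled rule each, for testing the filters.

Each fingerprint position $j$ maps to the toy atom pair $\{2j-1, 2j\}$ of
a molecule with $2m$ atoms, giving every bit a coherent substructure for
the atom-mapping stage. What the generator does **not** emulate: real
hashed-environment fingerprints (folding collisions, nested environment
bits, heavy-tailed bit frequencies) and real chemical series structure. A
green planted-recovery test therefore establishes that the pipeline
recovers *known discriminative bits under the stated noise model*, not
that it resolves real structure–activity relationships.

## Curation and class selection

`curate_records()` keeps a compound iff all assay annotations have
confidence 9, the molecular mass is within [250, 1000] Da, at least one
Kd/Ki/IC50 annotation has pPot > 5 (10 µM), no annotation has pPot ≤ 5
(an active/inactive mix is inconsistent and discarded), and no
interference/aggregator/medchem-rule flag is set. Rejections report the
*first* violated rule in the fixed order mass-range, confidence,
no-potency, low-potency, inconsistent-potency, flagged. The published
substructure catalogs behind the flags are out of scope; flags arrive
with the records.

`select_classes_by_similarity()` ranks classes by mean intra-class minus
mean inter-class Tanimoto similarity and omits the `k_omit` most
self-similar ones. Open choices resolved here: the summary statistic is
the arithmetic mean (configurable to median — the source does not say);
the inter-class value is computed against the pooled union of all other
classes; ties break by class id.

## Experimental design

`design_spec()` fixes a strictly increasing schedule of per-class
training sizes (default 12 sizes, 5 → 720 per class; the interior values
are not printed in the source and are configurable), `n_trials`
independent trials, and a constant balanced test set (default 100 per
class) drawn **first** and reused across all sizes of a trial — this is
what makes per-compound prediction patterns well defined. The validation
set is 20% of the training-set size, rounded half-up and forced to an
even per-class split with at least one compound per class (so 10 training
compounds get a 1 + 1 validation set). Training sets of different sizes
within a trial are sampled independently (not nested); the source states
only that sets were drawn randomly per size.

All randomness derives from one master seed through a hierarchical
key-mixing scheme (`dataset`, `split`, `job`, `grid`, `fit`, `background`
keys), so any job can be recomputed in isolation and resumed runs are
byte-identical.

## Models

Both learners are implemented in compiled code against their published
protocol; no pre-installed R learner covers them.

* **RF**: CART trees on binary features with gini or entropy impurity,
  per-node feature subsampling (`sqrt` or `log2` of $m$), optional
  bootstrap, `min_samples_split` ∈ {2..5}, `n_estimators` ∈ {100, 500}.
  Leaf probabilities are class fractions; the forest averages per-tree
  probabilities. A node with no impurity-reducing candidate split becomes
  a leaf.
* **SVM**: C-SVC solved by SMO (maximal-violating-pair working set) on a
  precomputed Tanimoto kernel $K(x, y) = c/(a + b - c)$, defined as 0
  when both fingerprints are empty. The cost grid has 14 distinct values
  0.1 … 10000 (the printed list contains one duplicated entry that is
  read as 7500), the stopping tolerance grid {1e-3, 1e-2, 0.1, 1, 2, 3}.

`train_model_with_search()` samples up to 50 settings uniformly *without
replacement* (the source does not specify; without replacement never
wastes a trial), ranks by validation MCC, breaks ties by the smaller
tie-break loss — log loss with probability clipping at $\varepsilon =
10^{-15}$ for RF, hinge loss on decision values for SVM — and remaining
ties by sampling order. MCC is defined as 0 when any denominator factor
is 0 (the source is silent); BA terms and F1 with zero denominators
contribute 0. The positive class of the confusion matrix and the 0/1 and
−1/+1 encodings are fixed alphabetically by class id.

## Exact Shapley values

The brute-force enumeration
$\phi_j = \sum_{S \subseteq F \setminus \{j\}}
\frac{|S|!\,(m-|S|-1)!}{m!}\,[v(S \cup \{j\}) - v(S)]$
(`brute_force_shapley()`, $m \le 15$) is the **normative definition**;
both production engines must reproduce it to 1e-10 and the test suite
enforces this on randomized cases.

**SVM.** The decision function $f(x) = \sum_i \alpha_i y_i K(x, s_i) + b$
is explained by linearity over per-support-vector *restricted-kernel
games*: $v(S)$ evaluates the Tanimoto similarity over the positions in
$S$ only, with $v = 0$ on an empty denominator (including $v(\emptyset) =
0$). This coalition game is this package's own reconstruction — the
source cites an external method without reprinting its formalism — and
the brute-force oracle, not any closed form, is the contract. Features
fall into at most four equivalence classes by $(x_j, s_j)$; $(0,0)$
features are exact dummies and the two mismatch classes share one value,
so the coalition sums collapse to $O(m^2)$ hypergeometric sums per
support vector (log-space binomials; every addend lies in [0, 1], so the
sums are numerically benign). The base value is the bias $b$.

**RF.** The *interventional* game is used: $v(S)$ is the mean, over a
background set $z$ (default: the model's training set), of the forest
probability of the composite taking $x$ on $S$ and $z$ elsewhere. Per
tree and per background row the recursion branches only at nodes where
$x$ and $z$ disagree; each reachable leaf contributes a closed-form term
(the Shapley value of a set-guard game), visiting every node at most
once. The base value is the mean background probability, and local
accuracy $\;b + \sum_j \phi_j = f(x)$ holds to machine precision.
Path-dependent tree-traversal variants are deliberately not offered: the
interventional game has clean axioms and a brute-force oracle.

Raw explanations are oriented so that positive values support the
alphabetically first class; `orient_explanation()` flips them toward a
compound's own class (probabilities map through $1 - p$, decision values
negate), so that downstream "positive = supports the true class" holds
everywhere.

## Aggregation

* **Prediction patterns**: the per-compound correctness bits across the
  size schedule classify into five categories (all-ones; all-zeros; a
  single 1→0 transition; a single 0→1 transition; variable). Over all
  $2^{12}$ bit vectors the categories count {1, 1, 11, 11, 4072}
  (exhaustively tested). Tabulation counts per (compound, pair, trial)
  occurrence, with distinct compounds reported separately, and the exact
  RF∩SVM intersection as a percentage of the RF count.
* **Instance cumulatives** split each oriented explanation's sum by
  feature status: $cs_{present} + cs_{absent} = f(x) - b$.
* **$f_{cs}$** is the difference of *medians* of $cs_{present}$ and
  $cs_{absent}$ over the correctly predicted test compounds of one class
  under one model; with no correct prediction it is an explicit NA
  marker, excluded and logged, never silently zeroed.
* **PCC** correlates $f_{cs}$ with model MCC per class over all models of
  a pair; zero variance (e.g. MCC constant at 1 on an easy synthetic
  world) yields the NA marker.
* **Combined PCC**: $|PCC_1| + |PCC_2|$ for RF, $PCC_1 + PCC_2$ for SVM,
  both read against a threshold of 1. The source is internally in tension
  about which side of the threshold marks the algorithm-specific pattern;
  the default maps combined ≥ 1 to pattern 1 (RF) / pattern 3 (SVM),
  consistent with the per-pattern PCC magnitudes, and
  `above_is_specific = FALSE` swaps the orientation. Pattern 3 is never
  emitted for RF, pattern 1 never for SVM.
* **Feature cumulatives** restrict to correctly predicted instances,
  normalize each attribution vector to absolute sum 1 (all-zero vectors
  are skipped and counted), and sum per feature and status within the
  class. "Contributions to correct predictions" is implemented as
  *instance* filtering, not sign filtering, matching the normalization
  text; both occurrence counts (per compound) and instance counts are
  recorded because the source's figure axis is ambiguous between them.
* **Top-k intersections** rank features per model, class and status by
  cumulative value (ties at rank $k$ break by feature index) and
  intersect the sets across models.

## The pipeline and its desk-scale defaults

`run_pipeline()` chains generate → curate → design → train → explain →
aggregate → map, writing one JSON artifact per job plus tidy CSV tables
and a `summary.json`. Aggregates are always rebuilt from the job files,
never from in-memory state, which is what makes interrupted-and-resumed
runs byte-identical to uninterrupted ones.

`pipeline_config()` defaults define the desk-scale benchmark used by the
acceptance suite: 64-bit fingerprints, 10 planted bits per class, 200
compounds per class, a 12-point schedule 5…100 per class, 3 trials, 50
test compounds per class, full hyperparameter grids with 50-trial random
search, and an RF-Shapley background capped at 64 training rows (drawn
deterministically per job; `rf_tree_shapley()` itself defaults to the
full training set). The schedule interior, the test-set size and the
background cap are this package's desk-scale choices, fixed once for a
single-CPU budget of minutes; the full published design (schedule to
720/class, 10 trials, 100 test compounds per class, uncapped background)
runs through the same code path by configuration.

On this easy planted world every model reaches MCC 1 at nearly every
size, so the per-class PCC is typically the NA marker (zero MCC
variance): the pattern and correlation machinery is therefore exercised
by constructed fixtures in the unit suite, and the pipeline's green
acceptance run establishes local accuracy, normalization exactness,
planted-bit recovery and MCC monotonicity — not non-trivial PCC values.

## Numerical choices

* MCC zero-denominator convention: 0. Log-loss clipping:
  $\varepsilon = 10^{-15}$.
* Local accuracy asserted at 1e-8 across full runs (measured ~1e-13);
  oracle equivalence at 1e-10.
* Atom-level neutral bin: $|\text{summed value}| \le \tau$ with
  $\tau = 10^{-6}$ (the source's "~ 0" is unspecified), configurable. A
  feature's value is added in full to *each* of its atoms; an even-split
  mode is available by flag.
* SMO: maximal-violating-pair selection, KKT gap stopping at the
  setting's `tol`, iteration cap 5·10^5; bias from free support vectors
  when any exist, otherwise the KKT-interval midpoint.
* Tie-breaks are deterministic everywhere (documented sort orders), so
  identical seeds give byte-identical artifacts.

## Known limitations

* No real-molecule hashing: fingerprints must be supplied as binary
  matrices (MTX/CSV readers provided); no RDKit bridge exists in R here.
* The SVM explanation is defined for the Tanimoto kernel only, and no
  approximate/sampled Shapley mode is offered, by design.
* The RF implementation is a faithful but independent CART ensemble; it
  is not numerically identical to other libraries' forests (split
  tie-handling and RNG differ), which is irrelevant to the contracts
  tested but matters if comparing fitted models across software.
* Class pairs only (binary classification); multi-class one-vs-one
  designs reduce to pairs via the manifest.
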