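---
title: "Protein-centric interaction prediction: model, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-centric interaction prediction: model, defaults and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`protint` predicts interaction partners of one target protein. This vignette
is the package's account of the underlying model, the defaults and the places
where the design was genuinely open — what was chosen and why.

## The statistical model

The task is binary classification of proteins: partners of the target
("positive") versus non-partners ("negative"). Each protein is summarized by
a frozen feature vector:

* 20 amino-acid composition fractions (counts normalized by sequence
  length, so the block sums to 1);
* one presence/absence indicator per functional-domain identifier in the
  training registry;
* optionally 400 dipeptide fractions (off by default — in our experiments,
  as in the broader literature on composition-based predictors, they add
  dimension without adding discrimination at these sample sizes).

The classifier is a soft-margin SVM with RBF kernel
$k(u,v) = \exp(-\gamma \lVert u-v \rVert^2)$ (libsvm, via e1071). Class
probabilities come from a Platt sigmoid fitted to *cross-validated* decision
values inside the training set, the standard way to avoid the optimistic
bias of calibrating on resubstitution values. The sigmoid fit is a
deterministic Newton iteration, so a trained model is bit-reproducible for
fixed data and seeds; this is also why the package performs calibration
itself rather than delegating to libsvm's internal (unseedable) calibration
path.

Single-feature relevance is scored by the F-score
$$F(i) = \frac{(\bar x_i^+ - \bar x_i)^2 + (\bar x_i^- - \bar x_i)^2}
             {s_i^{+2} + s_i^{-2}},$$
a between-class over within-class variance ratio. Degenerate features get
explicit conventions: $0/0 \mapsto 0$ (uninformative constant) and
$>0/0 \mapsto \infty$ (a within-class-constant perfect separator, ranked
first). Ties in the ranking break by ascending feature index so results are
deterministic.

## Assumptions and what they imply

* **Composition and domain content carry the signal.** The model sees no
  residue order (beyond optional dipeptides), no structure, no evolutionary
  profiles. Partners detectable only through structural epitopes or linear
  motifs will be missed.
* **Random background proteins are mostly non-partners.** Negatives are
  sampled uniformly from the proteome after excluding positives and their
  close homologs. Some sampled negatives may be unknown true partners; the
  label noise this introduces is assumed small.
* **Homology inflates performance estimates.** Training sequences with more
  than 70% identity are collapsed before training, and candidate negatives
  above 70% identity to any positive are excluded, so cross-validation folds
  are not linked by near-duplicate sequences.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| identity threshold | 0.70 | redundancy/homology cutoff (fraction identical over the shorter sequence; removal is strictly `> threshold`) |
| alignment scores | +1 / −1 / −1 | match / mismatch / linear gap for the global alignment |
| `C` ladder | $2^{-4} \dots 2^{4}$ | SVM regularization candidates |
| `γ` ladder | $2^{-10} \dots 2^{10}$ | RBF width candidates |
| feature counts | halving ladder $d, d/2, \dots, 16$ | F-score selection sweep |
| folds `k` | 5 | stratified cross validation |
| upsampling factor | 1 (range 1–5) | positive duplication before balancing |
| call threshold | derived | min assigned-class probability of correct training calls, floored at 0.5 |

## Numerical and procedural choices

* **Kernel form.** The squared-distance RBF is the default because it is
  what libsvm computes; the unsquared form
  $\exp(-\gamma\lVert u-v\rVert)$ is available via
  `rbf_kernel(..., squared = FALSE)` for comparison experiments.
* **Identity definition.** Identity is the number of identical aligned pairs
  in an optimal-score global alignment divided by the shorter sequence's
  length (the convention of greedy clustering tools). Among equal-score
  alignments the one with the most identities is used — computed exactly by
  a lexicographic dynamic program — so the value is well defined and
  symmetric. No k-mer prefilter or banding is used: exactness is preferred
  over speed at the scale this package targets.
* **Non-standard residues.** `B→D, Z→E, J→L, U→C, O→K`; `X` and `*` are
  dropped before composition, and the denominator counts retained residues
  only, keeping the 20-element composition well defined. Databases do not
  record how such residues "should" be treated for composition purposes;
  this mapping is the package's convention.
* **Domain registry provenance.** The indicator registry is the
  lexicographically sorted union of domains over the *whole* training set
  (both classes), then frozen. Building it from positives only would leave
  scan-time vectors ill-defined for domains seen only in negatives; unseen
  domains at scan time contribute nothing.
* **Fold construction.** Folds are stratified by class with total sizes
  differing by at most one (e.g. 137 samples split 28/28/27/27/27);
  assignment is a seeded shuffle followed by least-loaded placement, so it
  is deterministic per seed. Leave-one-out (`k = n`) is allowed as a
  degenerate case.
* **Nested selection by default.** F-score ranking is recomputed inside each
  set of training folds, so selection never sees held-out data.
  `global_selection = TRUE` reproduces the optimistic protocol (rank once on
  everything) that published pipelines sometimes use; the pipeline records
  which mode produced a report.
* **Upsampling semantics.** Upsampling duplicates positives exactly (no
  perturbation). By default all replicates of a source protein are
  constrained to one fold — otherwise each held-out replicate has exact
  copies of itself in the training folds and apparent accuracy inflates.
  `leaky_upsampling = TRUE` exposes that inflated protocol deliberately; on
  the strong synthetic preset at factor 5 it adds several accuracy points
  (the acceptance script measures the margin).
* **Grid ties.** Equal-accuracy cells resolve to fewer features, then
  smaller `C`, then smaller `γ` — the least complex model wins.
* **Threshold floor.** The derived call threshold is floored at 0.5 so a
  badly calibrated model can never call majority-negative scores positive.
* **Seeds.** Every stage derives its seed deterministically from the master
  seed by a counter scheme, so any single stage or repeat can be re-run in
  isolation and a full rerun is byte-identical.

## The synthetic generator

`generate_proteome()` emulates the four inputs a real study supplies: a
background proteome FASTA, an accession→domain table, a positive accession
list, and (optionally) a category map. Background sequences are i.i.d. draws
from Swiss-Prot-like residue frequencies with lengths uniform on 100–300;
domains are independent Bernoulli presences. The positive class plants two
kinds of signal: a multiplicative composition tilt (renormalized, so any
tilt strength keeps frequencies on the simplex) and a subset of domains with
elevated presence probability.

Three named presets fix the study conditions used throughout the tests:

* `null` — 50 positives + 150 background, no tilt, all domains at 0.05 in
  both classes. The pipeline should perform at chance; this calibrates the
  false-discovery behaviour of the whole stack, including the optimism of
  reporting the grid-search maximum (see limitations).
* `weak` — 60 + 200, cysteine ×1.5, 5 domains at 0.3 vs 0.05.
* `strong` — 60 + 400, cysteine ×3, 5 domains at 0.8 vs 0.05. Clearly
  recoverable signal; used for signal-recovery and leakage demonstrations.
  The 400-protein background leaves enough eligible negatives for balanced
  sampling at upsampling factor 5 (300 needed).

What the generator does **not** emulate: phylogenetic correlation between
sequences, realistic domain co-occurrence grammar, length/composition
coupling, annotation errors, or class imbalance in the positive list.
Passing tests on synthetic data therefore demonstrate that the machinery is
correct and calibrated, not that any particular biological interactome is
predictable at these accuracies.

## Problem sizes used in tests and the acceptance script

Test and acceptance runs use the preset sizes above (100–200 training
samples, 200–460-protein proteomes, 60-odd feature dimensions, the full
9×21 hyperparameter grid with a 3-step feature ladder). These sizes are the
package's chosen desk-scale study conditions: large enough that CV metrics
are meaningful at the reported precision, small enough that the entire suite
runs in minutes on one core.

## Known limitations

* The reported cross-validated accuracy at the grid optimum is the maximum
  over the search surface and is therefore optimistically biased; on the
  null preset it sits above 0.5 (typically 0.55–0.65) rather than at it. An
  unbiased estimate would need an outer CV loop, which is out of scope.
* Negative-sampling robustness is summarized across re-samplings, but the
  spread does **not** shrink as the eligible pool grows: sampling most of a
  small pool makes repeated negative sets nearly identical, which
  mechanically suppresses spread, while a large pool approaches the
  i.i.d.-draw variance. Intuition that a bigger pool "stabilizes" the
  accuracy distribution is wrong, and the tests assert only the robustness
  summary contract.
* Probability calibration with ~100 training points is coarse; derived call
  thresholds move noticeably between seeds. The threshold is reported with
  the count of correct training samples below it so users can judge.
* The greedy clustering is exact but quadratic; it targets positive sets and
  desk-scale proteomes (hundreds to a few thousand sequences), not
  whole-database clustering.
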