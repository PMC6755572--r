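---
title: "Non-linear nearest-neighbor QSAR: models, tuning and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-linear nearest-neighbor QSAR: models, tuning and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gknn)
```

## The modelling problem

Quantitative structure–activity relationship (QSAR) models predict the
biological activity of a chemical from its structure, leaning on the
similarity principle: structurally similar chemicals tend to have similar
activities. This package models *continuous activity scores* on a
`[0, 1]` scale — 0 clearly inactive, 1 clearly active — of the kind
produced by integrating many in vitro assays for a receptor endpoint
(e.g. estrogen-receptor agonist, antagonist or binding activity). A
score mixes potency with certainty: values near the extremes are
confident calls, mid-range values are uncertain.

The core estimator is the **generalized k-nearest-neighbor (GkNN)**
model. For a query chemical $i$, let $A_j$ be the activities of its $k$
most similar training chemicals and $S_{ij}$ their Tanimoto fingerprint
similarities. The estimate is a similarity-weighted power mean

$$\hat A_i = \left( \frac{\sum_j^k A_j^x\, S_{ij}^y}{\sum_j^k S_{ij}^y}
\right)^{1/x},$$

with two non-linearity exponents: $x$ acts in activity space (large $x$
pulls the estimate toward the most active neighbor; $x \to 0$ gives the
weighted geometric mean), and $y$ acts in structure space (large $y$
concentrates all weight on the most similar neighbor). Three classical
kNN variants are included for comparison: the arithmetic mean, the
geometric mean, and exponential distance weighting
$\sum_j A_j e^{-x d_{ij}} / \sum_j e^{-x d_{ij}}$ with
$d_{ij} = 1/S_{ij} - 1$.

Every prediction carries a confidence $q_i = \max_j S_{ij}$, the
similarity to the nearest training chemical — a simple applicability
domain proxy: estimates far from the training set are flagged, not
hidden.

## Numerical evaluation of the power mean

The tuning grid takes $x$ and $y$ up to 50, where the naive expression
$\left(\sum A^x S^y / \sum S^y\right)^{1/x}$ is numerically fragile.
The implementation works in the log domain:

$$\hat A = \exp\!\Big(\tfrac1x\big[\mathrm{logsumexp}(x\log A_j + y\log S_j)
 - \mathrm{logsumexp}(y\log S_j)\big]\Big),$$

restricted to neighbors with $A_j > 0$; zero-activity neighbors
contribute weight to the denominator but nothing to the numerator, which
is exact for every $x > 0$ (we define $0^x = 0$). Conventions at the
edges, chosen once and tested:

* $x = 0$ is the analytic limit of the power mean: the
  similarity-weighted geometric mean. A zero-activity neighbor with
  positive weight sends the limit to 0.
* $y = 0$ gives every neighbor weight 1 regardless of similarity
  ($0^0 = 1$), so `gknn(x = 1, y = 0)` is exactly the arithmetic kNN.
* If all neighbor similarities are 0 with $y > 0$, weights degenerate;
  the estimator falls back to the unweighted power mean with a warning.
* In the exponential model, $S = 0$ means infinite distance and zero
  weight; if every weight vanishes the most similar neighbor's activity
  is returned with a warning.
* The result is clamped to the neighbor activity range, making the
  documented boundedness invariant exact in floating point.

Tanimoto similarity of two all-zero fingerprints is defined as 1
(identical emptiness), of an all-zero against a nonzero fingerprint as
0; this avoids 0/0 while preserving identity.

## Fingerprints

Three binary fingerprint backends are available behind one
configuration object (`fp_config()`):

* `morgan` — a circular, ECFP-style fingerprint computed by the package
  itself: atom invariants seeded from (element, heavy-atom degree,
  bond-order sum, charge) are iteratively rehashed with sorted
  (bond order, neighbor invariant) pairs up to the chosen radius
  (default 2), and every (atom, iteration) invariant sets one bit after
  folding (default 1024 bits). Hashing uses an exact 31-bit polynomial
  scheme, so fingerprints are fully deterministic across platforms.
* `path` — OpenBabel's path-based FP2 (a Daylight-style linear-fragment
  fingerprint), via ChemmineOB.
* `maccs` — the fixed MACCS structural key set, via ChemmineOB.

Folding length barely matters beyond ~1000 bits: the tests verify that
1024- vs 16384-bit Morgan fingerprints change pairwise Tanimoto values
by less than 0.05. Defaults (Morgan, radius 2, 1024 bits) follow common
practice and keep similarity matrices cheap.

## Structure–activity landscape diagnostics

Ruggedness of the structure–activity landscape is measured by the SALI
index $\mathrm{SALI}_{ij} = |A_i - A_j| / (1 - S_{ij})$: structurally
close pairs with very different activities — activity cliffs — score
high, and it is exactly these pairs that bound how well any
similarity-based model can do. `sali_analysis()` reports all finite
pairs, the per-chemical maximum (which singles out cliff-forming
chemicals), and pairs with identical fingerprints ($S = 1$, index
undefined) separately rather than mixing an infinity into histograms.
SALI distributions use log-spaced bins because the values span orders
of magnitude.

Chemical-space overviews come from `similarity_distribution()` (the
radial-distribution-function analog over pairwise similarities) and
`eigenprojection()`, which diagonalizes the double-centered
self-similarity matrix — the kernel-PCA convention with the Tanimoto
matrix as kernel. We chose the similarity-matrix route over PCA on raw
fingerprint bits because it is independent of fingerprint length and
lets new chemicals be projected from their similarity rows alone; the
two routes are close relatives (for bit vectors the Tanimoto matrix is
a normalized inner-product kernel) but not identical, and the choice is
deliberately exposed here.

## Leave-one-out tuning

`grid_search()` runs leave-one-out cross-validation (LOO-CV) — each
training chemical predicted from all the others — for every
combination of family, $k$, $x$ and $y$. The default lists are
$k \in \{1,2,3,5,7,10,15,20,30,50\}$ and
$x, y \in \{0, 0.1, 0.2, 0.3, 0.5, 0.7, 1, 1.5, 2, 3, 5, 7, 10, 15,
20, 30, 50\}$, i.e. $10 \times 17 \times 17 = 2890$ combinations for
the GkNN family; the realized count is always reported.
Family-irrelevant parameters are collapsed (arithmetic/geometric sweep
$k$ only, exponential $k \times x$). The one engineering decision that
makes this tractable: the self-similarity matrix and the per-chemical
neighbor ordering are computed once and shared across all folds and all
grid points — LOO neighbor lists are just prefixes of the precomputed
ordering. A test verifies the cached sweep equals a naive
retrain-per-chemical loop to $10^{-10}$.

Parameterizations are ranked by a single composite score — the product
of balanced accuracy, accuracy and ROC AUC — computed after binarizing
scores at the activity threshold 0.1 (strict inequality: a score equal
to the threshold is inactive). Balanced accuracy guards against the
heavy class imbalance typical of screening endpoints; AUC uses the
continuous estimates (binarized predictions would make it degenerate),
with ties counted one half (Mann–Whitney convention). Metrics with
zero denominators are reported as flagged `NaN`, never silent zeros —
a silent zero would silently corrupt grid rankings — and an undefined
factor makes the composite score undefined, ranking such rows below
every defined one. Ties in the ranking are broken by family, $k$, $x$,
$y$ ascending, so sweeps are byte-for-byte reproducible.

## The synthetic-data generator

All tests run on seeded synthetic chemical sets; no downloads. Two
modes serve different purposes:

* `abstract_matrix` — no structures at all: latent points in the unit
  square define $S = 1 - d/d_{\max}$, so $1 - S$ is a genuine metric
  (triangle inequality holds). This is the mode for estimator, metric
  and landscape math, where expected values are computable by hand.
* `real_smiles` — a deterministic roster of valid SMILES enumerated
  from eight scaffold cores and twelve substituents, for everything
  that must touch a real parser and fingerprinter.

Activity landscapes:

* `smooth` — activity is a continuous piecewise-linear monotone
  function of similarity to a designated seed chemical, calibrated so
  that exactly `n_actives` chemicals exceed the 0.1 threshold in the
  noise-free case. The map mirrors curated training data: inactives lie
  in $[0, 0.01]$, actives in $(0.1, 1]$, and the uncertain band in
  between is empty — exactly what a training set looks like after
  mid-range scores are removed. Because $1 - S$ is a metric and the
  map's segment slopes are capped at 3 (the generator enforces a
  similarity margin at the class boundary and lets tightly clustered
  actives span less than the full $[0.101, 1]$ range), the finite SALI
  of every pair is bounded by the construction's Lipschitz constant
  ($\le 3$), reported as an attribute. A smooth fixture therefore can
  never cross the cliff-detection threshold of 4 used in the tests.
* `cliff` — smooth plus engineered cliffs: near-duplicate chemicals at
  similarity 0.9 with an activity gap of 0.9, forcing SALI $\ge 9$ for
  those pairs (in `real_smiles` mode the most similar
  distinct-fingerprint pairs are designated instead).
* `random` — i.i.d. uniform activities, a maximally rugged control.

Per-chemical source counts (1 + Poisson(5)) and binary per-source calls
are synthesized too — most chemicals get a 90% majority consistent with
their consensus activity, a seeded 20% minority only 60% — so the
source-consistency filters are exercisable end to end. One integer seed
drives everything through an isolated RNG scope; the global random
state is untouched, and identical specs are byte-identical.

What passing tests on these fixtures do **not** show: real chemical
sets have fingerprint similarities that are far less uniform than the
latent-point construction, activity landscapes that are not monotone
functions of similarity to any single chemical, and parser corner cases
(tautomers, salts, stereochemistry) the roster deliberately avoids.
The fixtures validate the machinery — estimator algebra, caching,
ranking, calibration — not chemistry.

## Problem sizes and numerical tolerances

Default test and acceptance runs use 10–60 chemicals for exactness
checks and a 200-chemical, 96-combination sweep for the
imbalanced-tuning demonstration — sizes at which brute-force oracles
(naive power-mean transcription, $O(n^2)$ AUC pair counting,
retrain-per-chemical LOO) remain exact and fast. Key tolerances:
reductions to closed forms at $10^{-12}$; log-domain vs naive
evaluation at $10^{-10}$ (moderate exponents) and vs a 50-digit
arbitrary-precision evaluation at $10^{-8}$ ($x = y = 50$); power-mean
limit bands of 0.05 at exponent 50; eigenreconstruction at $10^{-8}$.

## Known limitations

* Conversion of raw potency measurements (AC50 and relatives) to
  `[0, 1]` scores is out of scope; inputs must already be scored.
* No structure standardization beyond the parser's defaults, and no
  feature selection — conventional fingerprints only, by design.
* OpenBabel-backed fingerprints (path, MACCS) require at least one
  bond; single-atom molecules are only supported by the built-in
  circular fingerprint.
* The confidence $q$ is a one-number applicability-domain proxy; it
  flags distance from the training set but says nothing about local
  landscape ruggedness, which SALI diagnostics must assess separately.
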