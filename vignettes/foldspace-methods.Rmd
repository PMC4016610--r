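---
title: "Mapping protein structure space: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping protein structure space: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldspace)
```

Protein structure space (PSS) is the abstract space in which every solved
structure is a point and proximity means structural similarity. `foldspace`
builds *explicit* low-dimensional coordinate maps of this space from
pairwise alignment scores and then asks quantitative questions of them:
does a neighborhood in the map predict remote homology, and does an
unsupervised tessellation reproduce a curated clade system such as SCOP?
This vignette explains the underlying models, the tunable parameters, what
the synthetic generator does and does not emulate, and the numerical
decisions baked into the implementation.

## From alignment scores to distances

Structure aligners emit pairwise similarity scores `s_ij` (unitless,
aligner-specific; larger = more alike). Embedding needs dissimilarities, so
scores are subtracted from a maximum value. Taking the literal maximum would
let a few near-identical pairs dominate the scale, so the cap `s_n` is the
score at the `p`-th percentile rank: with `M = N(N−1)/2` scored pairs,

```
n = round_half_up(p/100 × (M + 1)),  clamped to [1, M],
δ_ij = s_n − s_ij   (s_ij < s_n),   δ_ii = 0.
```

* **`p` (percent, default 99.95).** The fraction of pair scores treated as
  "within scale". At the default, roughly 1 pair in 2,000 is capped.
* **Overflow mode.** Pairs scoring at or above `s_n` are *more* similar than
  the cap. The printed form of the piecewise definition assigns them the
  *maximum* distance `s_n`, which contradicts the subtraction idea (the most
  similar pairs would be the most distant); the package default `clamp`
  assigns them distance 0, and `literal` retains the printed behavior for
  fidelity experiments. This is the single deliberate deviation from the
  printed transform, and it is switchable.
* **Sparse sets.** The percentile ranks only *observed* pairs (Dali-like
  aligners score as few as 2% of pairs), and each unordered pair counts
  once.
* **Asymmetric inputs** are symmetrized first (mean by default; min/max
  available). Dissimilarity-polarity scores (e.g. a probability transform
  that is already a distance) bypass the transform entirely: diagonal forced
  to zero, negatives rejected.

## Classical scaling and SMACOF

Classical MDS double-centers the squared distances,
`A_ij = −½(δ²_ij − rowmean_i − colmean_j + grandmean)`, and eigendecomposes
`A`; coordinates are `X_ik = √λ_k ν_ik` over the `r` leading eigenpairs.
The solution is the best rank-`r` approximation of `A` in the least-squares
sense, but it does not minimize *stress*,

```
σ(X) = Σ_{i<j} w_ij (d_ij(X) − δ_ij)² ,
```

the quantity that actually measures distance reproduction. SMACOF
(scaling by majorizing a complex function) minimizes σ by iterating the
Guttman transform, which never increases stress. In the complete,
unit-weight case the update for point `i` is the average of
`x_j + δ_ij (x_i − x_j)/‖x_i − x_j‖` over all `j`, with the direction term
dropped for coincident points (the standard convention). With a 0/1 weight
mask the package applies the exact weighted transform `X′ = V⁺ B(X) X`
(Moore–Penrose pseudoinverse of the weighted Laplacian `V`), which reduces
to the simple average when all pairs are observed. The exact form was chosen
over per-row normalization heuristics because it preserves the monotone-
stress guarantee that the test suite asserts at every iteration.

Parameters that matter:

* **`r` (dimensionality).** The only free parameter of the representation.
  Experiments sweep `{3, 6, 12, 24, 30, 60, 90, 120}`; 12–30 is the useful
  plateau for classification, and 3 for visualization.
* **`tol` (default `1e-5`).** Convergence when `(σ_prev − σ_new)/σ_prev`
  drops below `tol`. `max_iter` (default 10,000) is a guard.
* **`init`.** `cmds` (default) converges in tens of iterations; `random`
  reaches the same stress but needs many more. The Procrustes statistic —
  residual sum of squares after optimal translation/rotation/reflection/
  scaling, normalized by the centered sum of squares of the target — is the
  yardstick for "same map up to similarity transform".
* **`missing`.** `weights` (default) fits only observed pairs, letting
  transitive relations place never-aligned structures; `impute-cap` /
  `impute-mean` fill the matrix first (required for classical MDS, which has
  no weighted form here).

Numerical conventions: eigenpairs are sorted by descending eigenvalue with
ties left in `eigen()` order; each eigenvector's sign is fixed so its
largest-magnitude component is positive (determinism); eigenvalues ≤ 0 give
zero coordinate columns rather than shrinking `r` — a negative eigenvalue is
a diagnostic of triangle-inequality violations in the input, not a reason to
change the declared dimensionality.

## ROC analysis and threshold selection

A map is evaluated as a binary classifier of shared annotation: pair
`(i, j)` is predicted related iff `δ_ij ≤ t` (ties inclusive). The gold
standard is the adjacency of a classification level — superfamily and fold
are the remote-homology levels of interest. The curve is computed
*exhaustively*: every unique observed distance is a threshold, plus one
sentinel below the minimum so the curve starts at (0, 0); AUC is the
trapezoidal integral, which equals the Mann–Whitney statistic
`P(δ_pos < δ_neg) + ½P(δ_pos = δ_neg)`. The operating threshold maximizes
TCR = TPR + TNR, with ties resolved to the smallest threshold (more
conservative neighborhoods); the sentinel is never selected. For sparse
matrices the pair universe excludes unobserved pairs by default; the
`unobserved = "infinite"` option keeps them as permanently-negative
predictions, which is the honest way to score a sparse *pairwise*
representation against a complete standard (98% of pairs simply cannot be
called).

Per-clade precision/recall/F1 use the pair universe "at least one member in
the clade": true positives are within-clade pairs inside the threshold,
false positives are mixed pairs inside it, so other clades' internal pairs
never pollute a clade's precision. Empty-prediction precision defaults to 1;
zero true positives give F1 = 0.

## Tessellation: neighbor joining + maximum linkage

The dendrogram is canonical Saitou–Nei neighbor joining with exhaustive
search of the Q-criterion; ties break to the lexicographically smallest
index pair, the final three-way join is kept as a (trifurcating) root, and
negative branch lengths are retained as computed (clustering never reads
branch lengths — only the original distances). Clusters are emitted by
recursive descent from the root: the first subtree (including the root
itself) whose descendant leaves all lie within `t` of each other becomes a
cluster. Raising `t` only merges clusters, never splits them, and labels
follow depth-first discovery order.

A consequence worth knowing: where the final join lands *inside* a large,
dense clade, that clade's members are distributed across the root's
children, and no single subtree contains exactly the clade — it fragments
even when all its pairwise distances are within `t`. This mirrors the
behavior observed on real fold data (some superfamilies do not correspond
to any single subtree) and explains why the cluster→clade direction of the
comparison statistics is systematically weaker than the clade→cluster
direction.

## Comparison statistics

Each source group maps to the target group with maximal Jaccard coefficient
`|A∩B| / |A∪B|` (the union form; the alternative with an intersection
denominator is treated as a typographical slip, since it is not bounded by
1). Ties break to the smallest target label. Summaries per direction:
max/mean/population-SD of the degrees of used targets, mean/population-SD of
the best-match Jaccard values, and `Ratio-1 = n_source/n_unique_targets − 1`.
`mean_degree × n_unique_targets = n_source` holds exactly, which is also the
arithmetic that makes published count ratios (e.g. 1180 : 612 ↦ mean degree
1.928, Ratio-1 0.928) internally consistent. Population (divide-by-n)
standard deviations are used so the table-style outputs are exactly
reproducible.

The degree diagnostic histograms per-structure alignment counts into
equal-width bins (default 100, matching the histogram convention used for
multi-thousand-structure sets) and fits `log10(frequency)` against
`log10(bin center)` over non-empty bins; zero-frequency bins are dropped
(log undefined). At a few hundred entities a √N bin count (~20) is the
statistically sensible choice and is what the validation suite uses.

## The synthetic generator

`generate_space()` emulates the statistical shape of a curated fold
hierarchy, not protein physics:

* fold centers ~ `N(0, fold_scale² I)` in `r_true` dimensions; superfamily
  centers ~ `N(fold center, superfamily_scale² I)`; members ~
  `N(superfamily center, member_scale² I)`. Defaults 10/3/1 give separable
  clades with realistic overlap at the superfamily fringe.
* clade sizes are Zipf-distributed (exponent 1.5; superfamilies per fold
  truncated at 10, members per superfamily at 100), reproducing the
  singleton-heavy size skew of real classifications — the default
  expectation is ~15 folds, ~38 superfamilies, ~270 members, with large
  seed-to-seed variation, which is itself realistic.
* distance noise is *additive on distances* (sd `noise_sd`, default 0.5,
  clamped at zero), so triangle-inequality violations can be injected
  independently of the geometry (`perturb_distances()` inflates a chosen
  fraction of pairs multiplicatively).
* sparsity masks assign each entity a Pareto(shape 1.5) weight and keep
  pairs with probability proportional to the weight product, calibrated by
  root-finding so the expected observed fraction hits the target; this
  yields hub-mediated, approximately scale-free alignment graphs. Very
  sparse masks can disconnect the graph; embedding is then ill-posed and
  analyses run on the largest component (`largest_component()`).
* all randomness flows from one seed through named substreams (hierarchy /
  noise / mask), so stages can be varied independently and every object is
  bit-reproducible.

What passing tests on this generator do **not** show: real alignment-score
distributions (score transforms of specific aligners are out of scope),
multi-domain chains, classification errors in the gold standard, or the
length-dependence structure of real aligner noise. Conclusions about method
behavior (exactness, monotonicity, recovery, sparsity robustness) transfer;
absolute AUC values do not.

## Validation problem sizes

The shipped validation suite runs classical-scaling exactness on 50 random
point sets up to N = 100; SMACOF monotonicity on 100 perturbed instances;
ROC/threshold agreement with brute-force oracles on 200 instances of up to
60 pairs; neighbor-joining recovery on 100 random additive trees of up to 8
taxa; tessellation against a brute-force subtree checker on 100 trees of up
to 12 leaves; and the full pipeline on the default synthetic space (~300
members) plus a 400-entity fixed-size space at 2% and 10% observation, with
weighted SMACOF capped at 2,000 iterations (its stress tail is flat long
before). These sizes were chosen so the entire suite validates the claims in
minutes on one CPU while keeping every check exhaustive at its scale.

## Known limitations

* Classical MDS requires a complete matrix; there is no weighted CMDS path,
  so very sparse inputs reach it only through imputation.
* The weighted SMACOF pseudoinverse is dense (O(N³) once per fit); the
  implementation targets thousands of entities, not hundreds of thousands.
* A single global threshold cannot capture clades of widely differing
  diversity — diffuse clades are recalled incompletely, large dense clades
  may fragment at the root (see above). Both effects are properties of the
  method, faithfully reproduced, not artifacts to be patched around.
* Neighbor joining assumes additivity; cluster-structured Euclidean data is
  not additive, so subtree boundaries are approximate even when distances
  are exact.
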