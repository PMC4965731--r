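---
title: "Topology-based disease-gene prioritization with nettop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-based disease-gene prioritization with nettop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nettop)
```

## The problem and the model

Disease genes are not scattered at random through molecular networks: they
tend to be hubs, members of dense complexes, or brokers between pathway
modules.  `nettop` turns that observation into a supervised learning
problem.  Every vertex of an undirected gene/protein network is described
by thirteen topological measures; a curated signature gene set provides
binary labels; tree ensembles learn the mapping; and feature-importance
analysis asks which aspects of network position actually carry the
disease signal.

Two statistical obstacles shape the whole design.  First, the labels are
heavily imbalanced — a few hundred disease genes against a genome-scale
vertex set — so plain accuracy is nearly meaningless and both the training
procedure (SMOTE, RUSBoost) and the reporting (G-mean, ROC/AUC) are built
for imbalance.  Second, centrality measures are strongly intercorrelated,
which limits how finely importance can be attributed; this is discussed at
the end.

## The thirteen measures and their conventions

All geodesics are unweighted (an edge counts 1) even on weighted networks;
edge weights enter only the random-walk transition probabilities and the
structural-hole tie proportions.  Networks are simple: self-loops are
dropped at parse time and parallel edges collapse to the maximum weight.

* **Degree** — number of incident edges.
* **Coreness** — largest k such that the vertex survives k-core peeling.
* **Clustering coefficient** — edges among neighbours over
  `deg (deg − 1) / 2`; 0 for degree < 2, where the ratio is undefined.
* **Betweenness** — the sum over *ordered* pairs (s, t) of the fraction of
  s–t geodesics with the vertex strictly interior.  Each unordered pair
  therefore counts twice; the value is exactly twice the textbook
  unordered-pair betweenness, and `halve = TRUE` recovers the latter.
* **Closeness** — the harmonic sum of reciprocal distances, with
  unreachable vertices contributing 0.  This keeps disconnected networks
  well defined without extracting the largest component.
* **Proximity prestige** — fraction of vertices able to reach v divided by
  their mean distance to v; 0 for an empty influence domain.
* **Barycenter score** — reciprocal of the total geodesic distance within
  the vertex's component; 0 for isolated vertices.  (Total-distance
  reciprocal was adopted over path-through counting, which betweenness
  already covers.)
* **Eigenvector centrality** — leading eigenvector of the adjacency
  matrix, unit norm, nonnegative.  Power iteration runs on `A + I`, which
  shares eigenvectors with `A` but makes the Perron root strictly dominant
  so bipartite structures cannot stall convergence (tolerance `1e-10` on
  the iterate, configurable).
* **Katz status index** — `((I − αAᵀ)⁻¹ − I)·1`, by direct dense solve.
  α must lie below `1/λ_max`; the default is half the critical value.
* **Subgraph centrality** — `Σ_k (A^k)_vv / k!`, the diagonal of
  `exp(A)`, via symmetric eigendecomposition.
* **Within-module z-score** — within-module degree standardized per module
  with the *population* standard deviation; modules with zero spread give
  z = 0.  Modules come from greedy modularity maximization by default
  (connected components are available as a degenerate alternative).
* **k-step Markov** — probability that a k-step random walk started
  uniformly over a root set (default: all vertices) ends at the vertex;
  the transition matrix is the row-normalized weighted adjacency,
  degree-0 vertices are absorbing, and k defaults to 6 steps.
* **Structural holes** — Burt's aggregate constraint
  `C_i = Σ_j (p_ij + Σ_q p_iq p_qj)²` over neighbours j, with proportional
  tie strengths.  The raw constraint is reported, not `1 − C`: low values
  mark brokers.

`compute_all()` emits the features in a fixed column order; all
column-wise tooling (serialization, labeling, SMOTE, training) keys on
column names, never position.

## SMOTE

`smote()` equalizes the class counts exactly.  Each synthetic positive is
`x + u (x_nn − x)` with one uniform `u ∈ [0,1)` per sample — a single
draw, not one per feature, so every synthetic point lies on the segment
between its two parents and hence inside the minority convex hull.
Neighbourhoods use Euclidean distance on raw features (k = 5, the
canonical SMOTE neighbourhood; a standardize-before-kNN flag exists and
defaults off).  The per-sample replicate count is `floor(deficit/n_min)`
with the remainder topped up by random minority draws.  Original rows are
never modified, and synthetic rows carry `provenance = "synthetic"` plus
`syn...` identifiers so leakage can be audited downstream.

## Classifiers

**Decision Tree Bagger** — `n_trees` (default 100) Gini-split trees, each
on an independent N-out-of-N bootstrap; the score is the fraction of
positive votes.  Trees are fully grown (minimum leaf size 1, no pruning):
bagging, not pruning, controls variance.  A bootstrap replica that misses
the rare class entirely yields a constant-vote stump.

**RUSBoost** — per boosting round, all minority rows plus an equal number
of majority rows sampled without replacement by the current boosting
weights; reweighting follows discrete AdaBoost, and rounds worse than
chance are skipped.  The score is the α-weighted positive-vote fraction.
Because RUSBoost undersamples internally, combining it with SMOTE is
refused with an explanatory error rather than silently double-sampling.

## Evaluation

Confusion-based metrics use threshold 0.5 on the ensemble score; ROC
sweeps all thresholds and the trapezoid AUC equals the Mann–Whitney
statistic (ties counted half).  Ratios with an empty denominator (e.g.
PPV with no predicted positives) are reported as 0 with the metric flagged
as degenerate, so downstream averaging never silently drops folds.

Cross-validation is stratified (default 10-fold) so the rare class is
present in every fold — the positive class would otherwise vanish from
some folds entirely.  SMOTE and backward elimination run strictly inside
each training fold; test folds contain only original rows.  Fold means
are reported as `M ± 1.96 σ_M` with `σ_M` the standard error over folds.

## Feature importance

*Gini importance* sums, over every split in every tree, the
node-size-weighted impurity decrease, unnormalized (no division by the
number of trees), so its magnitude grows with the ensemble and the
training set.  *Accuracy importance* is the mean decrease in out-of-bag
accuracy over 10 random permutations of a feature's column.  The
*combined score* `√(accuracy · Gini)` puts the two very differently
scaled measures on a common footing; tabular output rounds it to two
decimals.

`feature_importance()` additionally averages both importances over five
independently seeded fits (different bootstraps and SMOTE draws) before
combining.  With near-collinear centralities, a single ensemble assigns
the split credit within a correlated group almost arbitrarily; averaging
over fits removes the model-seed component of that variance (the
data-realization component remains — see Limitations).

*Backward elimination* greedily removes the feature whose removal
maximizes the cross-validated G-mean and proceeds while the score does not
decrease, stopping only when every removal would lower it.  The
non-worsening (rather than strictly-improving) rule is deliberate: a
constant or pure-noise column never changes a split, so its removal ties
rather than improves, and a strictly-improving rule could never discard
it.  Ties among candidate removals drop the feature with the lower
combined score first.

## The synthetic study generator

`generate_network()` grows a preferential-attachment graph: a complete
seed on m vertices (m = 2 by default), then each arriving vertex attaches
to m distinct existing vertices with probability proportional to degree —
connected by construction, with exactly `m(m−1)/2 + (n−m)m` edges and the
heavy-tailed degree distribution characteristic of protein-interaction
networks.  `plant_labels()` standardizes the features named in
`effect_weights`, draws a latent score `Σ w_f z_f + ε` with
`ε ~ N(0, noise_sd)`, and labels the top `⌈positive_fraction · n⌉` latent
scores positive.  Top-quantile labeling (rather than Bernoulli draws)
makes the positive count exact and the downstream class-balance tests
deterministic.  Defaults: n = 1000, positive fraction 0.04 (mirroring a
few-hundred-gene signature at genome scale), noise 0.5.

The default effect weights are `degree = 4, structural_holes = 2`.  The
sign choice is substantive: on preferential-attachment graphs the
constraint is strongly anti-correlated with degree, so a *positive*
constraint weight loads the labels onto the constraint's
degree-independent component — disease genes are predominantly hubs, with
a secondary preference for vertices whose neighbourhoods are cohesive and
redundant (the complex-membership picture).  With both weights in
opposite signs the two terms would collapse onto a single degree axis and
the second driver would carry almost no independent signal.

What the generator does *not* emulate: co-expression weight matrices,
pathway-annotation structure, assortativity patterns of curated
interactomes, or study-bias artifacts (well-studied disease genes having
inflated degree).  Passing tests therefore demonstrate that the machinery
is correct and that planted topological signal of realistic shape is
recoverable — not that any particular real network carries such signal.

## Problem sizes and numerical choices

The test-suite exercises measure-by-measure correctness on exhaustive
small graphs (every connected graph family up to 8 vertices that the
oracles enumerate by brute force: explicit path enumeration, per-k
peeling, truncated matrix series, dense solves) and runs the full
pipeline at n = 1000 with five generator seeds — large enough for a
heavy-tailed degree distribution and a 40-gene signature, small enough
that all-pairs BFS and 10 × 100-tree fold fits stay comfortable on one
CPU.  Floating-point test tolerances: 1e-9 absolute for path-based
measures and constraint, 1e-10 for the Katz solve, 1e-8 for eigenvector
agreement, 1e-12 for AUC identities.  Degenerate-input conventions
(isolated vertices, zero-spread modules, empty denominators, single-class
bootstrap replicas) are fixed by definition rather than left to error,
and each is unit-tested.

## Limitations

* **Importance attribution among collinear measures is intrinsically
  unstable.**  On scale-free networks, k-step Markov centrality at k = 6
  is numerically almost proportional to degree (r ≈ 0.999), and the
  clustering coefficient tracks the degree-independent part of the
  constraint.  Tree ensembles split credit within such proxy groups
  essentially at random across data realizations: in replicate synthetic
  studies the two planted drivers rank in the top 3 of 13 in roughly half
  of single studies, and even 5-study-averaged rankings can place the
  secondary driver third or fourth depending on the replicate set.  The
  primary driver (degree) is recovered essentially always.  Conclusions
  about *groups* of correlated measures are robust; conclusions about
  individual members of a group are not.
* **SMOTE's benefit is regime-dependent.**  With a strong planted signal,
  fully grown bagged trees saturate with or without balancing; the median
  G-mean improvement from SMOTE appears once label noise is substantial
  (the suite demonstrates it at noise_sd = 4).
* Labeling matches identifiers exactly (after whitespace trimming); no
  alias or cross-namespace resolution is attempted, so signature genes
  absent from the network namespace are silently unmatched (the matched
  count is logged).
* Geodesics ignore edge weights by design; a weighted-geodesic variant
  would change the five path-based measures.
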