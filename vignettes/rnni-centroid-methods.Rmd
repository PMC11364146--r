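---
title: "Mean trees in RNNI space: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean trees in RNNI space: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treecentroid)
```

## The model

A *ranked tree* on `n` taxa is a rooted binary tree whose internal nodes are
totally ordered by the times of the corresponding divergence events: node
ranks are unique integers `1..n-1`, no node outranks its parent, and leaves
sit at rank 0.  We encode a ranked tree canonically as its rank-ordered
cluster sequence — `clusters[[i]]` is the leaf set below the rank-`i` node —
because the geometry below is cluster-centric: equality, hashing, and the
cluster property on paths all reduce to operations on this sequence.

**RNNI space** is the graph whose vertices are all
`n!(n-1)!/2^(n-1)` ranked trees on a fixed taxon set and whose edges are:

* *rank moves*, swapping the ranks of two unconnected nodes with consecutive
  ranks (in the cluster encoding: swapping two disjoint consecutive
  clusters), and
* *NNI moves*, acting on an edge joining nodes of consecutive ranks by
  moving one of the two sister clades below the bottom node to the other
  side of the top node, ranks unchanged.

The RNNI distance is shortest-path length in this graph.  Each
consecutive-rank pair contributes one rank-move neighbour or two NNI
neighbours, so every tree has between `n-2` and `2(n-2)` neighbours.

Given a sample 𝒯 of `m` ranked trees, the **mean (centroid) tree** is a
minimiser of the sum of squared distances (SoS, a Fréchet variance)
`SoS(T) = Σ_{S∈𝒯} d(T,S)²`.  Because RNNI space has positive curvature,
gradient-style averaging schemes that work in nonpositively curved
treespaces do not transfer directly; the package instead uses a discrete
local search.

## Algorithms

**FindPath.**  Distances and shortest paths are computed by FindPath.  With
working tree `U` initialised to the source, destination clusters are
processed in rank order `k = 1..n-2`; while the most recent common ancestor
of cluster `C_k` in `U` has rank `r > k`, it is pulled down one rank: by a
rank move when the nodes at ranks `r-1, r` are unconnected, otherwise by the
NNI move on that edge after which the ancestor of `C_k` has rank `r-1`.
Exactly one NNI variant qualifies — one sister clade of the bottom node is
disjoint from `C_k` — and the implementation asserts this at run time,
aborting with a diagnostic rather than silently emitting a non-shortest
path.  The move count is the distance; the complexity is O(n²) per pair.
Correctness is not taken on trust: the test suite checks FindPath lengths
against breadth-first search over the exhaustively built graph (all pairs at
n = 4 and 5, and 200 random pairs at n = 6), verifies the metric axioms on
random triples, and confirms the cluster property on every emitted path.

**Centroid.**  Plain hill descent: evaluate `SoS` for every neighbour of the
current tree, move to a neighbour with *strictly* lower SoS (the minimum;
exact ties between minimal neighbours are broken uniformly with the seeded
RNG and logged), stop when no neighbour improves.  Strict improvement —
plateau moves are disallowed — guarantees termination, since SoS is a
non-negative integer that decreases every iteration; it also means the
iteration count is bounded by the starting SoS.  Neighbour evaluation may be
parallelised (`workers`); candidates are collected first and the tie-break
applied to the deterministically ordered minimal set, so the result is
independent of the worker count.  The output is a *local* optimum: on
multimodal samples different starts can end in different basins.  The test
suite pins this phenomenology with a frozen 6-tree sample on 5 taxa that has
several distinct local optima (SoS 61 vs 88 from two recorded starts), and
conversely shows that the minimum over all-starts runs equals the exhaustive
global minimum on full small spaces.

**Sturm-style start.**  The descent starts, by default, from an iterative
shrinking-step estimate: draw the sample in seeded random order without
replacement; initialise `T` to the first draw; at iteration `k`, with `p`
the FindPath path from `T` to the next draw `R`, set `T` to the tree at
distance `floor(d(T,R)/k)` along `p`.  The `1/k` step is the classical
Sturm schedule; once `floor(d/k)` hits 0 the estimate stops moving.  One
design point deserves note: the step rule is stated here as *distance/k*
because a step of literally `floor(1/k)` would be zero for every `k ≥ 2`,
freezing the estimate at the second draw; the fraction-of-the-path reading
is the one consistent with the shrinking-step idea and with the remark that
a zero step leaves `T` unchanged.  On concentrated samples this start is
measurably better than a uniform random tree (compared by Monte-Carlo in
the tests) and typically lands within a few moves of the optimum.

## Branch lengths and the MCC baseline

The centroid is a ranked topology; applications need time trees.
`annotate_rank_heights()` assigns the rank-`i` node the arithmetic mean of
the rank-`i` node heights across the sample — the mean *t-coordinate* —
deliberately ignoring which leaves sit below the node.  Means of strictly
increasing vectors are strictly increasing, so this annotation can never
reorder the summary's nodes.  That is the property that motivates it:
conventional clade-based annotation (`common_ancestor_heights()`, provided
as the baseline's annotator) averages the heights of each clade's most
recent common ancestor across the sample, and those averages can violate
the summary's rank order; when they do, the package flags the result
(`monotonic = FALSE`) instead of silently re-ranking.

`mcc_topology()` implements the maximum clade credibility baseline:
candidates are the distinct rooted topologies *occurring in the sample*, and
the score is the sum of log posterior clade frequencies over non-trivial
clades.  Whether one multiplies raw frequencies or sums logs does not change
the argmax; log space is used for numerical stability, and the root clade
(frequency 1) is excluded, which is value-neutral.  Exact score ties are
broken towards the earliest sampled occurrence and flagged.

## Input handling

Trees are parsed with ape (Newick; NEXUS with translate tables).  Inputs
must be rooted, binary, with non-negative branch lengths; violations are
reported with the offending tree's index.  Non-ultrametric trees are made
ultrametric by extending leaf branches to the maximum root-to-leaf depth,
which leaves internal node times untouched and puts all leaves at height 0,
matching the ranked-tree convention that leaves have rank 0.  Burn-in is a
fraction (`floor(burnin * m)` leading trees dropped) rather than a count, as
a fraction transfers across thinning choices.

Ranking requires strictly ordered node heights, but real posterior files
contain ties.  The default policy is to fail loudly; `tie_policy =
"perturb"` instead breaks ties by the lexicographically smallest leaf label
of each tied cluster — an arbitrary but deterministic total order — nudges
the tied heights apart by a relative epsilon (1e-9), and warns.  This is a
pragmatic choice, not a claim about how any other implementation resolves
ties.

## Comparison metrics

`compare_trees()` reports, against a reference tree: clade age error (CAE)
and clade rank error (CRE) — the mean over the reference's `n-1` clades of
the absolute height (resp. rank) difference between the clade and its most
recent common ancestor in the summary —, the RNNI distance raw and divided
by the treespace diameter, the rooted Robinson–Foulds distance (symmetric
difference of non-trivial clade sets), and the weighted RF (clade-indexed
absolute branch-length differences over the clade union, absent clades
contributing their full length).  Two readings of CAE/CRE were defensible —
averaging over the truth's clades only, or symmetrising over both trees —
so the truth-referenced form is the default (it is the natural "error
against the truth") and `symmetrize = TRUE` provides the other.

The normalising diameter is `(n-1)(n-2)/2`.  This closed form is not
assumed: all-pairs BFS over the full treespace gives diameters 1, 3, 6, 10
for n = 3..6, the formula reproduces these, and the test suite re-runs that
gate; `rnni_diameter()` uses BFS-certified values for n ≤ 6 and the gated
formula above.

`correlation_diagnostics()` relates geometry to externally supplied per-tree
scores (the package computes no likelihoods): per-tree SoS against score, or
pairwise distances against absolute score differences, each normalised by
the largest observed value; both Pearson and Spearman coefficients are
reported and constant inputs are rejected rather than returning NaN.

## Synthetic data: what a green test establishes

The generators state the testing world explicitly:

* `random_ranked_tree()` — exactly uniform over ranked topologies via
  uniform pair-merging (the coalescent without times); uniformity is
  checked by a chi-square test over all 18 four-taxon trees at 18 000 draws.
* `random_walk_sample()` — m independent walks of `s` uniform moves from a
  centre (`s` fixed or Poisson; default experiments use n = 8, m = 100,
  Poisson(3), emulating a concentrated, roughly isotropic posterior cloud).
  The simple walk is not stationary-uniform and is not used as if it were.
* `jitter_heights()` — a fixed topology with rank heights `1..n-1` plus
  truncated Gaussian noise (default sd 0.1 height units; violating draws
  resampled), for annotation tests with a known target and a
  `3·sd/sqrt(m)` recovery bound.

These clouds are unimodal and isotropic by construction.  Real posteriors
are not: they mix topology modes, correlate heights with topology, and put
mass on near-tied node orders.  A green recovery test therefore establishes
correctness of the machinery on its stated world — not that the centroid
outperforms any other summary on real MCMC output, which would require
likelihood evaluation that is deliberately out of scope.

## Limitations

* Local search: single-start results can be non-global optima (by design;
  multi-start is the user's loop over seeds, and all tied optima found are
  reported only insofar as seeds expose them — no completeness claim).
* How many distinct mean trees a sample can admit is an open question; the
  package makes no attempt to enumerate them.
* Exhaustive tooling (`enumerate_space()`, `bfs_distance()`, BFS diameters)
  refuses n > 7; beyond that the validated closed form stands in for the
  diameter.
* Rank-height annotation is a heuristic with good empirical behaviour, not
  a consistent estimator of node ages; `common_ancestor_heights()` is kept
  precisely so the two schemes can be compared on the same topology.
* No sampled-ancestor, multifurcating or unrooted trees; no likelihoods,
  no MCMC.
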