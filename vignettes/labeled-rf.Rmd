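---
title: "An edit distance for event-labeled gene trees: model, algorithms, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An edit distance for event-labeled gene trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labeledRF)
```

## The model

A gene tree annotated by reconciliation carries, on every internal node,
one of two event labels: speciation (`SPE`) or duplication (`DUP`).
labeledRF works with rooted or unrooted multifurcating trees whose
internal nodes all have degree at least 3 (the root may have degree 2),
with uniquely named leaves. Branch lengths are irrelevant to the
distance and are discarded on input.

The distance between two such trees on the same leaf set is the minimum
number of unit-cost edit operations transforming one into the other:

* *contraction* of an internal edge whose endpoints carry the same
  label (the merged node keeps it);
* *extension*, the exact inverse: move a subset `X` of a node's
  neighbors, `2 ≤ |X| ≤ degree − 2`, onto a new node copying the label;
* *flip* of one internal node's label.

Two conventions are worth making explicit. First, contracting a *mixed*
edge (endpoints labeled differently) is not a single operation — a flip
must pay for it. Second, we close the tree class under edits: an
extension may not leave a node of degree 2, since such nodes do not
represent evolutionary events. The operation set is symmetric
(contractions and extensions are mutual inverses, flips are
involutions), which makes the distance a metric; the test suite checks
the metric axioms exhaustively on the full 5-leaf labeled space (162
trees) against an independently built graph of single-edit moves.

Intermediate trees along an edit path are *not* required to be
consistent with any species tree; the labels are treated as abstract
binary annotations.

Rooted trees are handled through the standard dummy-leaf device: attach
a pendant leaf to the root and forget the root. The clade-based RF
distance of a rooted pair equals the bipartition-based RF distance of
the dummy-extended unrooted pair, and the same correspondence is used
for the labeled distance (`unroot_with_dummy()`; both trees must use
the same dummy name, default `"__ROOT__"`, chosen to avoid collision
with biological identifiers).

## Why labels change the algorithmics

For unlabeled trees, RF distance is simply the number of *bad* edges —
internal edges whose bipartition the other tree lacks — summed over both
trees, and an optimal edit path never touches a *good* (shared) edge.
With labels this breaks down: the bundled `fig3_pair()` instance is a
hub with three label-alternating chains whose single good edge separates
one chain from the rest. Handling the two bad subtrees separately costs
9 flips + 17 contractions + 17 extensions = 43 operations, but
contracting the *good* edge too lets all three chains share flips:
6 flips + 18 contractions + 18 extensions = 42. Exactness is therefore
not claimed anywhere; the package computes certified upper bounds plus
an exact oracle for small instances.

## The algorithms

**Optimal contraction of one tree.** The number of contractions needed
to reduce a tree to a star is fixed (its internal edge count), so only
flips matter. For a mixed tree the minimum is
`ceiling(diam/2) − 1`, where the diameter is the edge-length of the
longest leaf-to-leaf chain: flipping a node `v` of minimum eccentricity
and contracting its incident internal edges reduces `ecc(v)` by one per
round, and `min ecc = ceiling(diam/2)` always. `contract_tree()` first
contracts all non-mixed internal edges (free of flips), then runs this
midpoint procedure; `tree_geometry()` exposes the eccentricities.
The final star label equals the midpoint's label flipped
`ecc − 1` times, so enumerating all midpoints yields the achievable
star labels: for odd diameter two adjacent midpoints with opposite
labels always exist, making both labels reachable; for even diameter
the label may be forced. `preferred_final_label` picks among the
achievable ones; ties between midpoints break deterministically toward
the smallest node id.

**Preprocessing.** Any *bad* edge whose endpoints share a label can be
contracted first — this provably lowers the true distance by exactly 1
(the test suite verifies the drop on 200 random 6-leaf pairs against
the oracle). Since such contractions change no labels and remove only
their own bipartition, the classification of all other edges is
unaffected; `contract_nonmixed_bad_edges()` therefore classifies once
and contracts in canonical edge order.

**Decomposition and the per-pair heuristic.** After preprocessing, the
internal nodes of each tree split into maximal bad subtrees (connected
components under bad edges, bounded by good and terminal edges); the
boundary bipartitions identify a unique partner subtree in the other
tree, and the pairing covers every internal node
(`decompose_bad_subtrees()`). `methodology2()` contracts both sides of
each pair to a single node with the midpoint procedure, coordinating
the two final labels: if the two sides' achievable label sets
intersect, a common label is chosen (deterministically the
alphabetically first); otherwise each side takes its first achievable
label and one closing flip is charged to the pair. Whether that closing
flip is avoidable when both sides have forced labels (both even
diameter) is not known in general; the implementation charges it
without claiming optimality. Good edges are never contracted here. The
total is at most twice the exact distance; the acceptance suite
measures the worst observed ratio over 50 seeded random 6-leaf pairs
(typically ≤ 1.5).

**The star path.** `star_path_cost()` instead contracts *both whole
trees* to stars (good edges included), joins them with at most one
flip, and replays the second contraction backwards as extensions. On
instances like `fig3_pair()` this is strictly better.
`labeled_rf_estimate()` computes both and returns the cheaper witness,
with ties going to the per-pair heuristic (the published strategy);
both totals are reported for transparency. Since each strategy emits a
complete edit script that `replay()` checks step by step, every
estimate is a certified upper bound; the per-pair total alone carries
the factor-2 guarantee, and the minimum inherits it.

**Witness scripts.** Scripts are sequences of `FLIP`/`CONTRACT`/`EXTEND`
operations on node ids. Ids are stable under replay: a contraction
keeps its first endpoint's id, an extension appends a fresh id. The
t2-side operations are reversed into extensions by aligning the two
reduced trees node-by-node via their clades seen from the
smallest-named leaf.

**The exact oracle.** `exact_distance()` runs breadth-first search over
labeled trees identified by a canonical key (the lexicographic minimum
of recursive serializations rooted at each internal node — leaf names
anchor the recursion, so isomorphism is decided with leaves fixed, as
the distance requires). The explored neighborhood structure is cached
per leaf-name universe for the session, so simulation studies that
issue hundreds of queries on the same six leaves pay the exploration
once. The search bound defaults to a safe additive bound (bad edges
plus internal node counts); the oracle is exact but exponential and
intended for at most about 7 leaves — the CLI refuses larger inputs
without `--force`.

## The simulator and what it does (not) emulate

`random_labeled_tree(n, multifurcation_rate)` grows a binary topology
by sequential uniform leaf attachment, contracts each internal edge
independently with the given probability, and labels internal nodes
independently and equiprobably. It emulates the *shape* of annotated
gene trees (multifurcations, interleaved event labels) but not their
biology: real duplication nodes cluster along specific lineages, real
trees are far from label-equiprobable, and sequential attachment is not
the uniform distribution on tree space. Conclusions from passing tests
are therefore about the algorithms' correctness and guarantees, not
about performance on any particular gene family.

`random_edit()` draws one operation: with probability 0.3 a uniformly
random internal node is flipped; the remaining mass is spread uniformly
over all contractible edges (equal-label endpoints) and all expandable
nodes (degree > 3). Two conventions are simulator choices documented
here because no external specification fixes them: an extension's
moved subset is drawn by choosing a size uniformly in
`2:(degree − 2)` and then a uniform subset of that size, and when the
0.7-mass pool is empty (e.g. a fully mixed binary tree) the edit falls
back to a flip. All randomness flows through R's global RNG; `mutate()`
and `evaluation_run()` accept an explicit seed and are byte-reproducible
under it.

`evaluation_run()` applies edits one at a time and records, after each,
the classical RF distance and the labeled estimate against the base
tree. On a 30-leaf base tree with up to 10 edits and 30 replicates (the
sizes used by the acceptance suite) the labeled estimate's mean
absolute error against the true edit count is several times smaller
than classical RF's, and classical RF never exceeds the labeled
estimate row-wise (it cannot: every labeled path must still repair all
bad bipartitions). The estimate usually stays at or below the true edit
count, but unlike the row-wise RF bound this is an empirical tendency,
not a guarantee.

## Numerical and interface choices

* Bipartitions and clades are canonicalized as sorted comma-joined
  leaf-name strings (the side containing the globally smallest name),
  making set algebra order-free and deterministic.
* Newick output emits children in canonical order (smallest descendant
  leaf name first), so serialization is reproducible; equality of trees
  is always labeled-topology isomorphism, never node-id equality.
* Two label codecs cover the common encodings: internal node names
  (case-insensitive `spe`/`speciation`, `dup`/`duplication`) and NHX
  `D=N`/`D=Y` tags. Inputs with degree-2 internal nodes are rejected
  unless `suppress_unary = TRUE`, which splices them out and discards
  the label.
* Degenerate inputs: star trees have diameter 2 and need 0 flips;
  single-node regions are forced to their own label; identical trees
  yield empty scripts and distance 0.

## Problem sizes in the test suite

Exhaustive checks run on the complete 5-leaf labeled space (162 trees);
oracle-backed comparisons use 6-leaf trees (50 heuristic-ratio pairs,
200 preprocessing pairs, roughly 3,000 reachable states per leaf set);
flip-optimality is brute-forced on sampled mixed trees of 5–7 leaves;
the simulation benchmark uses a 30-leaf base tree, 10 edits and 30
replicates. These sizes keep the full suite under a few minutes while
every claim tied to a printed quantity is still computed, not assumed.

## Limitations

* The heuristic is a 2-approximation, not exact; even on the bundled
  worked example neither strategy is proven optimal.
* Only two labels are supported; larger event alphabets (losses,
  transfers) would change both the operations and the contraction
  theory.
* No branch-length- or weight-aware variant is provided, and no
  NNI-based improvement of bad-into-good edges is attempted.
* The exact oracle is exponential and deliberately capped to small
  leaf sets.
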