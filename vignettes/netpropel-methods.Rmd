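---
title: "Methods: out-of-core network propagation for function prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: out-of-core network propagation for function prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpropel)
```

## The model and its assumptions

netpropel ranks proteins by relevance to a functional class with a t-step
random walk on a weighted undirected functional network. Writing **W** for
the symmetric adjacency matrix, **D** for the diagonal weighted-degree
matrix and *C* for the seed set of class-annotated proteins, the walk
starts from `p0 = 1/|C|` on seeds and iterates `p(t+1) = t(Q) %*% p(t)`
with `Q = D^-1 W`. The assumptions are the usual ones of
guilt-by-association: edge weights are (noisy) measures of functional
relatedness, class membership is locally smooth over the network, and the
seed annotations are correct. The walk is run for a small, fixed number of
steps (1–3) rather than to stationarity: after many steps the vector
forgets the seeds and approaches a degree-dominated profile, so short walks
are both cheaper and better suited to AFP.

The update resolved at one vertex,
`p_i(t+1) = sum_j d_jj^-1 * w_ji * p_j(t)`, touches only the vertex's
incident edges and its neighbours' previous-step values. That locality is
what the rest of the design exploits.

## Out-of-core execution

The graph is stored on disk: vertex ids are split into K contiguous
intervals; each interval owns a shard file holding every arc whose
destination lies in the interval, sorted by source (fixed 16-byte
little-endian records, a JSON manifest with per-file md5 checksums). Each
undirected edge is stored as two directed arcs; on an undirected network
one direction would suffice, but the duplication keeps the traversal
uniform at the cost of doubled (cheap) disk space.

A full pass loads one interval's shard into memory and advances a sliding
window over each other shard to reach the interval's out-arcs; because
records are source-sorted and intervals are processed in order, every
window advance is a single seek, so a pass needs at most K reads per
interval and K² per pass. The traversal counts its non-sequential reads
and the test suite asserts the bound on every test graph. Window reads that
would return zero records are skipped (and not counted), which only
tightens the bound.

Per-vertex state — the inverse weighted degree and the two probability
buffers — lives in an in-RAM global vector: it is O(n) while the edges are
O(n·degree), so even networks with millions of edges need only megabytes of
RAM for state.

Execution is strictly synchronous (Jacobi): within a pass every update
reads only previous-step neighbour values, and the two buffers swap roles
when the pass completes. An asynchronous (Gauss–Seidel) mode would converge
differently depending on K and visiting order; the synchronous mode makes
the result bit-for-bit identical across K and across repeated runs, which
the tests verify, and is the semantics the double-buffered per-vertex state
encodes. Rather than alternating which buffer is read on odd/even
iterations, the implementation physically swaps the buffer roles each
pass — observationally equivalent and simpler to reason about.

## Network construction

*Classical Jaccard.* Each data type yields a binary profile per protein
(domains, motifs, keywords, ...); every protein pair is scored
`|A ∩ B| / |A ∪ B|`. Two empty profiles score 0, not NaN — a deliberate
choice that keeps the networks sparse and avoids asserting similarity from
shared absence.

*Hierarchical Jaccard.* For GO annotation profiles, terms are weighted by
specificity: weight `1/(d+1)` where d is the term's distance from the
leaves, so leaves weigh 1, their parents 1/2, and so on. Distance is
computed as the minimum number of child-edges from the term down to any
leaf, in the ontology as supplied. Two open choices were resolved as
follows: (a) distance is measured in the supplied ontology, not in an
annotation-induced sub-DAG — the caller can restrict the ontology first if
desired; (b) annotation profiles are *not* ancestor-closed by default;
`propagate_ancestors()` applies the true-path closure explicitly when
wanted. Both choices are the least-surprising ones: they compute exactly
what the inputs say.

*Integration.* Data-type networks are combined by the unweighted average:
the consensus weight of a pair is the mean of its weights over the n
networks, with a pair absent from a network contributing 0. No
sparsification is applied by default; a `min_weight` cutoff is available.

*Class filtering.* Terms are retained when they annotate at least
`min_positives` proteins (at least 20 in the intended use, so that
cross-validation folds keep enough seeds), with an optional upper bound
(e.g. a 20–100 window) for restricting to moderately sized classes.

## Multi-species assembly

Per-species networks are mutually disconnected blocks of the merged graph.
Clusters of orthologous proteins (NOGs) supply the joins: clusters are
restricted to a chosen core species set, only *consistent* clusters —
exactly one protein per represented species — are kept, and all member
pairs of each kept cluster are connected as a clique. The weight of these
orthology edges is not dictated by any data source; the default is 1.0
(configurable), and a pair that already has an edge keeps the larger of the
two weights, making augmentation monotone and idempotent — it can reconnect
components but never deletes or weakens an edge.

## Evaluation

Per term, a stratified F-fold (default 5) cross-validation: folds balance
positives and negatives to within one; each fold's walk is seeded with the
training-fold positives only; held-out vertices' scores are pooled across
folds (every vertex is scored exactly once, while held out) and the pooled
vector is summarized by AUC (Mann–Whitney form with midranks, so ties are
handled exactly) and precision at the smallest rank cutoff reaching each
requested recall (ranking ties broken by vertex id, deterministically).
Pooling rather than per-fold averaging is the default because with 20–100
positives a per-fold ROC rests on very few positives; a per-fold mean is
easy to compute from the returned fold assignment if wanted. Negatives are
all non-annotated vertices.

Method comparisons use a paired two-sided Wilcoxon signed-rank test on the
per-term metric, at α = 0.01. Zero differences are dropped; with ≤ 25
non-zero pairs the p-value comes from the exact null distribution of the
signed-rank sum, computed by convolution over the (mid)ranks — this stays
exact under tied absolute differences, where the textbook no-ties
distribution does not apply; with more pairs a normal approximation with
tie correction and continuity correction is used.

## Synthetic data: what it emulates, and what it does not

The generators produce the structure the method assumes, fully determined
by one integer seed (sub-generators use fixed seed offsets so adding one
never perturbs another):

- `gen_planted_partition()`: modules of proteins with dense intra-module
  connectivity (default 4 modules × 30 proteins, `p_in = 0.25`,
  `p_out = 0.02`; intra weights uniform on [0.5, 1], inter on
  [0.05, 0.3]). The defaults make direct neighbours informative about
  class membership, the regime in which a 1-step walk excels.
- `gen_profiles()`: module-specific feature blocks with independent bit
  flips; at zero noise, within-module Jaccard is exactly 1 and
  cross-module exactly 0.
- `gen_toy_ontology()`: complete trees whose level structure makes the
  `1/(d+1)` weights known in closed form.
- `gen_multispecies()`: one planted-partition network per species (default
  4 species × 3 modules × 20 proteins), merged without any cross-species
  edge; consistent NOGs spanning one protein per species per module slot;
  annotations emitted only for the first half of the species (80% coverage
  within them). The per-species blocks are deliberately sparse
  (`p_in = 0.08`, mean intra-module degree ≈ 1.5): real single-species
  networks are sparse and partly fragmented, and that sparsity is
  precisely why cross-species orthology edges help — with dense blocks,
  single-species prediction saturates and the multi-species comparison
  becomes uninformative.

What the fixtures do *not* emulate: heavy-tailed degree distributions,
correlated noise between data types, hub proteins, annotation bias toward
well-studied genes, or realistic GO DAG shapes. Passing tests on these
fixtures therefore demonstrate the *correctness* of the machinery (store,
engine, walk, constructions, metrics) and the qualitative behaviour of
propagation under the assumed structure — not expected performance levels
on real proteomes.

## Numerical choices and degenerate inputs

- Zero-degree (dangling) vertices get inverse degree 0, so mass reaching
  them vanishes at the next step. The update rule is applied literally and
  the leak is documented and tested rather than hidden; `renormalize =
  TRUE` rescales the vector to sum 1 after each step when leak-free scores
  are wanted. Score vectors on positive-degree graphs conserve mass to
  1e-12 over the tested horizons.
- Convergence mode: when `tol` is supplied, iteration stops when the
  max-norm change falls below it (default when used: 1e-6); otherwise a
  fixed step count is run. Seed scores are not clamped; evaluation handles
  seed exclusion by design (held-out scoring).
- Shard intervals are balanced by arc count, not vertex count, since arcs
  are what occupy memory during a pass; K is an explicit parameter (with an
  optional per-shard arc budget) because no rule for choosing it is implied
  by the data.
- Self-loops, duplicate pairs with conflicting weights, and non-positive
  weights are rejected at load time: the similarity networks of this domain
  are simple graphs by construction.
- All ranking ties (in `rank_vertices()` and in precision-at-recall) break
  ascending by vertex id, so every reported number is reproducible
  bit-for-bit.

## Problem sizes used in tests and the acceptance script

The test suite exercises the oracle equivalence on 100 random graphs
(n ≤ 200, density ≈ 0.05, seeds of size 1–20, t ∈ {1,2,3}, K ∈ {1,2,7}),
K-independence on 20 graphs, and the multi-species comparison on 20
generated replicates; the acceptance script re-runs the same computations
with a 30-graph oracle sweep. These sizes give the property checks many
independent chances to fail while keeping a full run around half a minute.

## Known limitations

- Shards are written once; the store does not support graph mutation,
  concurrent writers, compression or memory-mapped I/O.
- Only the synchronous execution mode exists; algorithms that require
  asynchronous updates are out of scope.
- The walk has no restart/damping parameter and no kernelized variants.
- The evaluation harness applies no multiple-testing correction across
  terms; its per-term outputs can be fed to any correction downstream.
- OBO parsing is not included: the ontology arrives as a child→parent TSV.
```{r}
sessionInfo()
```
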