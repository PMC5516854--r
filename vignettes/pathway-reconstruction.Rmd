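---
title: "Reconstructing signaling pathways with k-shortest paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing signaling pathways with k-shortest paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kspathr)
```

## The model

Signal transduction starts at membrane receptors and ends at transcriptional
regulators (TRs). Given a weighted directed interactome $G = (V, E)$ with
probability-like edge weights $w_e \in (0, 1]$, a receptor set $S$ and a TR
set $T$, we score a path by the **product of its edge weights** and seek the
$k$ highest-scoring loopless paths that start in $S$ and end in $T$. Two
modeling assumptions matter:

* **Weights compose multiplicatively.** Treating $w_e$ as (approximately
  independent) confidences, a chain of interactions is only as believable as
  the product of its links. Long paths are penalized automatically; there is
  no separate length prior.
* **Endpoints, not interiors, are constrained.** Receptors and TRs may be
  traversed as intermediates of other paths; only a path's first and last
  node are required to be in $S$ and $T$. No edges around $S$ or $T$ are
  removed.

An artificial source $s$ gets a zero-cost edge to each receptor, an
artificial sink $t$ a zero-cost edge from each TR, and each real edge the
cost $c_{uv} = -\log(w_{uv})$. Costs are nonnegative, and minimizing the
summed cost of an $s \leadsto t$ path is equivalent to maximizing the
product score. We use the natural log: any base preserves the ordering, and
$e$ makes $\mathrm{score} = \exp(-\mathrm{cost})$ exact (asserted to 1e-9 in
the tests).

## The algorithm

`yen_ksp()` is standard Yen's algorithm over the augmented graph: after each
accepted path, every prefix (root) of that path defines a spur search in
which the next-edges of all accepted paths sharing the root, and all root
nodes except the spur node, are banned; candidate deviations accumulate in a
pool keyed by their full node sequence (so a path can never be emitted
twice) and the minimum by (cost, lexicographic node sequence) is accepted
next. Returned costs are nondecreasing; each path records its 1-based
emission index.

The spur searches are accelerated with A*. `reverse_distances()` runs one
Dijkstra pass over the edge-reversed graph from $t$, giving every node's
*exact* remaining cost $h(v)$ to the sink. Exactness implies consistency
($h(u) \le c_{uv} + h(v)$), and since Yen's bans only remove edges and
nodes — which can only increase true distances — $h$ remains admissible in
every spur search. A* therefore returns the same paths as Dijkstra while
popping far fewer nodes: it stops as soon as $t$ is popped, and nodes with
$h = \infty$ (no route to $t$) are never enqueued. The test suite asserts
that `use_astar = TRUE` and `FALSE` produce identical path sequences; the
speedup is measured informally but never asserted, since it depends on the
graph.

**Degenerate paths.** A protein that is both a receptor and a TR induces an
$s \to x \to t$ path with no real interaction. Reconstruction edges must be
real interactions, so such paths are dropped after the k-shortest-paths run
and the survivors re-indexed contiguously; ranked outputs have no gaps.

**Ranking.** Every node and edge is ranked by the index of the first path
containing it. Within one path index, edges keep their position along the
path, but evaluation treats all items of one index as a tied block: the
within-path order is an artifact of traversal, not evidence.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 20000 | paths computed; reconstructions are nested in `k`, so larger values only extend the ranking. The default suits genome-scale interactomes where paths reuse edges heavily; use small `k` for small graphs. |
| `clamp_epsilon` | off | substitute for weights $\le 0$ on ingest (keeps $-\log w$ finite); weights $> 1$ are always rejected. |
| `neg_ratio` | 50 | sampled negatives per positive in evaluation; held fixed across methods being compared. |
| `teleport` | 0.5 | RWR restart probability onto $S$ (domain $(0, 1]$; at 1 the stationary distribution is exactly uniform on $S$, a closed form the tests use). |
| `tol`, `max_iter` | 1e-10, 10000 | RWR power-iteration stop: L1 change below `tol`, else an error reporting the residual. |

## Evaluation protocols

* **Negatives** are drawn uniformly without replacement from the
  interactome edges outside the pathway, `round(neg_ratio * |positives|)` of
  them, from a sorted pool under a fixed seed — reproducible given (seed,
  universe, positives) regardless of input order.
* **Pathway-adjacent negatives** (distance 1: at least one endpoint is a
  pathway protein) can be excluded *before* subsampling; such interactions
  are plausibly under-curated pathway members, and removing them can only
  remove false positives. Distances use the undirected skeleton, since
  adjacency is about the participation of pathway proteins, not signal
  direction: distance 0 is a true positive and distance $1 + d$ means the
  nearer endpoint is $d$ undirected hops from the pathway.
* **Block-tied precision-recall**: at each distinct first-path index,
  precision $TP/(TP+FP)$ and recall $TP/|positives|$ after the whole block
  enters; ranked items that are neither positive nor negative are ignored.
* **Protein-level evaluation** ranks nodes by first-path index; node
  positives are the pathway proteins and node negatives the endpoints of the
  sampled negative edges that are not pathway proteins. Note the sampling
  asymmetry this creates: a 50× edge subsample covers a small fraction of
  the edge universe, while its endpoints cover most nodes. Protein- and
  edge-level curves are therefore compared *at matched recall* (precision as
  a function of recall), the scale on which PR curves are conventionally
  read.
* **Aggregation** over pathways is micro-level: items are tagged by pathway
  (the same interactome edge in two pathways is two items), pooled, and a
  single curve computed.
* **Role perturbation** deletes or adds `round(fraction * |set|)` members
  (seeded, independently for $S$ and $T$) to probe robustness to wrong
  annotations.

**The RWR baseline** restarts on $S$ with probability `teleport`, otherwise
moves along out-edges proportionally to weight; dangling nodes teleport.
Edges are ranked by descending flux $f(u,v) = p(u)\, w(u,v) / \sum_x
w(u,x)$. Published RWR variants differ in restart-set composition and edge
ranking; this implementation is a documented stand-in with explicit
parameters, and its stationary vector is verified in the tests against a
dense linear solve of $(I - (1-q)(M + r d^\top))\,p = q\,r$.

## The synthetic world

`fixture_spec()` defaults describe the reference recovery setting: a
200-node directed Erdős–Rényi background at density 0.05 with weights
$U(0.05, 0.4)$, five receptors, five TRs, and five planted
receptor→intermediate→TR chains with weights $U(0.7, 0.95)$. Two deliberate
choices make recovery *provable* rather than merely likely:

* **Planted chains are two edges long** (one intermediate). The worst
  planted-path score is $0.7^2 = 0.49$, while any path using a background
  edge scores at most $\max(0.4,\; 0.95 \times 0.4) = 0.4$. With longer
  chains a single direct background receptor→TR edge (weight up to 0.4)
  could outrank a three-edge planted chain ($0.7^3 = 0.343$), and the
  100%-recovery property would become statistical.
* **Intermediates are distinct across chains.** If two planted chains
  shared an intermediate, "crossover" paths made entirely of planted edges
  could outrank a genuine planted chain and push some planted edge beyond
  the first $|planted|$ path indices. Chains may still share receptors and
  TRs (roles are assigned round-robin, so every receptor and TR lies on at
  least one chain), which mimics pathway convergence at the endpoints.

What the generator does **not** emulate: scale-free degree distributions,
curation noise, edge-direction ambiguity, or genome-scale size. A green
recovery test establishes that the algorithm and ranking are correct on a
separable instance — not that reconstruction of real curated pathways
reaches any particular precision.

Generation is a pure function of the spec; the PRNG (Mersenne–Twister) is
recorded in the metadata sidecar the CLI writes. Numeric streams are only
guaranteed reproducible within R.

## Numerical choices

* Costs and scores of a returned path are recomputed edge-by-edge along the
  node sequence, so their arithmetic is bit-identical to an oracle summing
  in the same order, and sorting is stable across code paths.
* All lexicographic tie-breaks (Dijkstra pops, predecessor choice, Yen's
  candidate selection, output files) use C-locale byte order, making outputs
  locale-independent. Equal-cost candidate paths order by (cost, node
  sequence); float equality is exact, which is deterministic because tied
  candidates arise from identical arithmetic.
* Weight validation rejects $w \le 0$ by default rather than clamping,
  because $-\log(0)$ is undefined and silent clamping would hide data
  errors.
* Parallel duplicate edges collapse to the maximum weight (the most
  generous evidence wins); undirected input edges expand to both directions
  at equal weight, the standard reduction when mixing physical and directed
  regulatory interactions.

## Limitations

* The engine is pure R with an $O(V^2)$ search per spur; it is comfortable
  at the scale of the test fixtures (hundreds of nodes, tens of paths) but
  not intended for a 150k-edge interactome at $k = 20000$ — the algorithm
  is the contribution here, not the constant factor.
* Only the raw PR curve is produced; no interpolation or area summary.
* Identifier namespaces are opaque: no mapping between gene/protein
  identifier systems is attempted.
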