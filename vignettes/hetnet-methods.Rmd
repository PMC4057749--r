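---
title: "Methods: topology, hubs and modules of heteroreceptor networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology, hubs and modules of heteroreceptor networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetnet)
```

## The scientific problem

G protein-coupled receptors (GPCRs) do not act only as monomers: protomers
of different receptors assemble into heteromers whose pharmacology differs
from either partner alone. Treating each experimentally supported
protomer–protomer interaction as an undirected edge yields a
*heteroreceptor network*. The curated human GPCR network of this kind
comprises 156 protomers and 260 heteromer pairs, dominated by
rhodopsin-like (Class A / F1) receptors, with strong intrafamily
connectivity and a small set of highly connected receptors (DRD2, OPRM,
ADRB2, the adenosine and opioid receptors) holding the network together.

This package implements the full analysis pipeline for such networks:
normalisation, topological profiling, network-model classification, hub
identification under four criteria, and MCODE-style dense-module
detection, together with seeded generators that emulate the statistical
structure of the curated network so that every stage can be validated
without access to the original (online-only) edge list.

## Graph normalisation

Raw interaction records are noisy: reciprocal detections produce both
A–B and B–A rows, and homodimer records produce self-loops. `hetnet()` /
`normalize_graph()` upper-cases identifiers, removes self-loops, and
merges duplicate unordered pairs. Merging unions the evidence-method tags
but takes the **maximum** of the publication counts (the union of the
underlying publication sets is unknowable from counts, and support should
never be inflated) and ORs the `controversial` flag. Isolated nodes —
protomers known to the attribute table but without any heteromer edge —
are retained and enter every denominator (density, P(k), relative
connectivity), because disconnected protomers are a real feature of these
networks (23 of the 156 curated protomers are disconnected).
Normalisation is idempotent.

## Topological metrics

All metrics treat the graph as undirected and simple.

* **Degree** k and the distribution `P(k)` = (nodes of degree k)/N,
  including k = 0.
* **Local clustering** `C(n) = 2 n_l / (k (k − 1))`, with `n_l` the edges
  among n's neighbours. For k < 2 the formula is undefined; we set
  C(n) = 0 **and keep those nodes in the global mean**, matching the
  convention of the standard interactive network-analysis platforms, so
  that global values are comparable with published ones. `C(k)` averages
  C(n) over nodes of degree k.
* **Density** D = 2E/(N(N−1)) and average degree 2E/N.
* **Paths**: breadth-first shortest paths; the histogram, mean path
  length and diameter are taken over *connected unordered pairs only*.
  Disconnected pairs are excluded rather than treated as infinite — a
  network with isolated nodes would otherwise have no finite diameter,
  whereas published analyses of such networks report one.
* **Relative connectivity** f = |largest component|/N.
* **Edge share** of a node subset: edges with at least one endpoint in
  the subset, over E. For an independent (mutually non-adjacent) subset
  this equals the subset's degree sum over E, which is the convention
  under which "the nine most-connected protomers carry 42% of all links"
  type statements are made.

## Network-model classification

Three reference architectures are distinguished by how P(k) and C(k)
behave: *random* networks have Poisson-like P(k) and degree-independent
C(k); *scale-free* networks have P(k) ~ k^−γ; *hierarchical* networks
are scale-free with C(k) ~ k^−1. We fit, on the raw unique-k points:

* a least-squares line on (log10 k, log10 y) — the power law, γ = −slope;
* a least-squares line on (k, y) — the linear competitor;

and compute R² = 1 − SS_res/SS_tot on the same transformed points used
for each fit. Raw points (no CCDF, no logarithmic binning, no
maximum-likelihood estimation) are a deliberate fidelity choice: the
published fit statistics for this class of analysis arise from simple
fits to the plotted distributions, and reproducing their meaning matters
more here than statistical best practice.

The decision rule (`classify_network()`):

1. if R²(power) − R²(linear) on P(k) < δ → **random**;
2. else if the C(k) power-law exponent is within `gamma_tolerance` of −1
   and its R² ≥ `ck_r2_threshold` → **hierarchical**;
3. else → **scale-free**.

The published analyses state no thresholds, so these are package design
choices, config-exposed with defaults δ = 0.1, `gamma_tolerance` = 0.3,
`ck_r2_threshold` = 0.7. They were chosen so that the three generator
families are cleanly separated (an Erdős–Rényi bump fits neither model
well, so the margin rule sends it to *random*; preferential attachment
gives a strong P(k) power law with flat C(k); the Ravasz-style
construction adds the C(k) ~ 1/k signature) — the generator-recovery
tests verify ≥80% correct recovery over seed ensembles. Distributions
with zero variance on the fitted scale are flagged `degenerate` and
refused a label rather than scored: R² is meaningless there.

Whether R² for the power law should be computed in log–log or raw space
is genuinely open; log–log space is used because that is the space in
which the line is fit.

## Hub criteria

Four alternative hub definitions are implemented:

* **degree > t** for t = 5 and t = 8 (classic fixed thresholds);
* **top 95% of the high-degree nodes**: the top ⌈(1−q)·N⌉ nodes of the
  descending degree sequence (nearest rank), with ties at the realized
  cutoff included. A uniform degree sequence makes the criterion
  degenerate (all nodes tie); this is flagged rather than hidden;
* **relative connectivity**: order nodes by decreasing degree (ties by
  ascending id, for determinism — the procedure is otherwise
  order-ambiguous), grow prefix subgraphs G₁ ⊂ G₂ ⊂ …, and compute
  f_k on each. Hubs connect predominantly to non-hubs, so while hubs are
  being added f falls; the first k with f_k > f_{k−1} marks the natural
  hub/non-hub boundary and the hubs are the nodes of G_{k−1}. The
  comparison is done in exact rational arithmetic (cross-multiplied
  integers), not floating point. If f never rises (e.g. any complete
  graph), the stop condition never fires and the result is an empty hub
  set with status `"no boundary found"` — a fact about the criterion, not
  an error;
* **degree = 1 non-hubs**, the complement view of the periphery.

All criteria accept a plain (`id`, `degree`) table as well as a graph, so
published degree tables can be analysed directly.

## MCODE-style module detection

Dense modules are found in three stages, with every constant exposed:

1. **Vertex weighting**: weight(v) = k_max × density of the highest
   k-core of v's closed neighbourhood (the core-clustering coefficient);
   nodes with degree < `degree_cutoff` (default 2) get weight 0.
2. **Complex prediction**: seed at the highest-weight unvisited node,
   BFS-include neighbours with weight ≥ seed_weight × (1 −
   `node_score_cutoff`) (default 0.2). Nodes join at most one complex,
   making clusters node-disjoint and ranks reproducible.
3. **Post-processing**: drop candidates lacking a `k_core_filter`-core
   (default 2); optionally *fluff* (add boundary neighbours with dense
   closed neighbourhoods; off by default, applied before the haircut);
   *haircut* (default on) iteratively removes members with fewer than two
   within-cluster neighbours — equivalently, restricts the candidate to
   its 2-core, which is why the haircut is idempotent. Members are
   finally restricted to the component containing the seed, keeping every
   cluster connected. Score = density × size; ranking is by decreasing
   score, ties by size then seed id.

Tie-breaks everywhere are (weight, degree, ascending id); with them the
whole pipeline is deterministic. Note that high-weight bridge nodes can
legitimately pull two dense regions into one complex (the expansion
inequality is about vertex weights, not connectivity); the test suite
pins this behaviour on a bridged double-clique.

## Synthetic generators: what they emulate

`gen_random()` (Erdős–Rényi G(n,p)), `gen_scale_free()` (preferential
attachment growing from a complete m-clique, so E = m(n−m) + C(m,2)) and
`gen_hierarchical()` (Ravasz-style recursive clique replication with
peripheral-to-root wiring; N = base_size^levels) provide the three model
families for classification validation.

`gen_hetnet_like()` realises graphs matching the *published summary
constraints* of the curated GPCR network — its defaults are those
conditions: 156 nodes, 260 edges, 23 isolated nodes, 57 degree-1 nodes,
top degrees (17, 17, 13, 12, 11, 10, 10, 10, 10). The degree sequence is
completed with filler degrees confined to [2, min(top_degrees) − 1] (so
the degree-1 and top blocks stay exact), realised by deterministic
Havel–Hakimi construction, then randomised by seeded degree-preserving
rewiring. `top_independent = TRUE` removes any edge between two
top-degree nodes by double-edge swaps, so the top nodes' edge share
equals their degree sum over E — the convention behind the published 42%
link share. Family labels are drawn at 82%/10%/8% (F1/F2/F3, the curated
composition) and greedily swapped towards intrafamily edges, emulating
the strong intrafamily dominance (219 + 15 + 17 intrafamily vs 9
interfamily pairs).

What the generator does **not** emulate: the true wiring of the curated
network (only its summary statistics), its clustering structure (no
published intra-cluster densities exist to target), or the per-edge
evidence annotations (publication counts and the ~6% of controversial
pairs live only in the unpublished per-pair records; the schema carries
the fields, the generator leaves them empty). Consequently, passing tests
demonstrate that the *procedures* are correct under the published
marginal constraints — not that any synthetic realisation reproduces the
real network's mesoscale results (its diameter of 9, clustering
coefficient 0.25, its 3 relative-connectivity hubs, or its 10 detected
modules), which require the withheld edge list.

## Numerical choices and degenerate inputs

* Percent-style quantities are rounded half away from zero at the
  printed precision (`percent_share()`); R's banker's rounding would
  disagree with conventional reporting on exact halves.
* The top-percentile rank ⌈(1−q)·N⌉ is computed after rounding away
  binary-representation noise ((1 − 0.95) × 20 is 1 + 4·10⁻¹⁶ in
  floating point and must not ceiling to 2).
* The f-trajectory stop test compares integer cross-products, never
  floats.
* Empty graphs, edgeless graphs and all-equal degree sequences raise
  informative errors or degeneracy flags rather than NaNs; path metrics
  on a pair-free graph are NA with a warning in the profile, and errors
  in the strict per-metric functions.
* Average degree is reported as 2E/N throughout.

## Problem sizes used in validation

The validation suite runs entirely on synthetic data: exhaustive oracle
comparison on all 64 labelled 4-node graphs plus 200 seeded random graphs
of up to 30 nodes; generator-recovery ensembles of 20 seeds per model
(Erdős–Rényi n = 1000, preferential attachment n = 500, hierarchical
125 nodes); and constraint-exact realisations of the published 156-node
summary. These sizes make the whole suite run in about a minute while
keeping every property at full strength.

## A worked run

```{r example, eval = FALSE}
report <- run_pipeline(list(generator = list(kind = "hetnet_like"), seed = 42))
glance(report$profile)
glance(report$clusters)
tidy(report$hubs$relative_connectivity)
write_report(report, "hetnet_report")
```

## Known limitations

* The classification thresholds are calibrated on the three generator
  families; networks near the random/scale-free boundary (weak tails,
  few distinct degrees) will be sensitive to δ.
* Least-squares log–log fitting is a faithful reproduction of the
  published methodology, not a statistically efficient power-law
  estimator; do not use the γ estimates for inference about tail
  exponents.
* MCODE results depend on all tie-breaks only through ranks; cluster
  *membership* can shift between tied seed orders on adversarial graphs.
* `gen_hetnet_like()` requires jointly satisfiable constraints and will
  refuse (with the violated arithmetic condition) rather than
  approximate.
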