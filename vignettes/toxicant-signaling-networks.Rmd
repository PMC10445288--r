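---
title: "Reconstructing and testing toxicant signaling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and testing toxicant signaling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgelinker)
```

## The model

A chemical that perturbs a cell binds receptors at the membrane; the
signal travels through protein–protein interactions to transcription
factors (TFs) that reprogram expression. High-throughput screens such as
ToxCast report, per chemical, which receptors and which TFs respond — but
not the intermediate signaling path. This package reconstructs that path
on a background interactome, a directed weighted graph $G = (V, E, w)$
whose nodes are proteins and whose edge weights $w(u,v) \in (0,1]$ grow
with the amount of experimental evidence for the interaction.

Given the responsive receptors $S_x$ (sources) and responsive TFs $T_x$
(targets) of chemical $x$, the cost of an edge is $-\log w(u,v)$, so the
cheapest path is also the highest-scoring path (score = product of
weights). For **every edge** $(u,v) \in E$ the algorithm finds the
cheapest source-to-target path *through that edge*:
add a super source $s$ wired to every member of $S_x$ and a super target
$t$ wired from every member of $T_x$ (all with weight 1, cost 0); run
Dijkstra from $s$ and, on the edge-reversed graph, from $t$; the best
path through $(u,v)$ then costs $d_s(u) + c(u,v) + d_t(v)$ and is the
concatenation of the two shortest-path segments around the edge. Distinct
edges often share a best path; duplicates are kept once. Ranking the at
most $|E|$ distinct candidates by increasing cost and keeping the top $k$
yields the toxicant signaling network. Because each retained path is the
optimum for at least one edge, raising $k$ adds at least one new edge
whenever another candidate exists — with continuous weights, ties that
could break this have probability zero. This is the property that
motivates the per-edge formulation over plain $k$-shortest-paths, whose
next path may contribute no new edge at all.

### Paths are walks, strictly speaking

The two Dijkstra segments are computed independently, so their
concatenation is a *walk*: in rare configurations the $s \to u$ segment
and the $v \to t$ segment share a node and the "path" revisits it. The
construction is exactly the cheapest walk through the edge (with
nonnegative costs each segment alone is simple), and that is what the
tests verify edge-by-edge against exhaustive enumeration; whenever the
produced candidate happens to be node-simple — the overwhelmingly common
case — it provably equals the cheapest *simple* path through the edge,
and the tests assert that too.

## Statistical significance

The null hypothesis: the number of high-scoring source-to-target paths
depends only on the degree of each protein, not on which proteins
interact. The null model swap-randomizes the interactome: repeatedly pick
two edges $(a,b), (c,d)$ and replace them with $(a,d), (c,b)$, rejecting
self-loops and duplicates, preserving every in/out-degree. Directed and
undirected edges are swapped in separate pools (a swapped edge is also
rejected if it would collide with the other pool, keeping the
no-duplicate-edge invariant of the combined graph). Weights travel with
the tail's outgoing slot, preserving the weight multiset per pool. Each
randomized interactome uses 10 accepted swaps per pool edge by default —
enough mixing for the small graphs used in tests; the count is
configurable because no universal mixing constant exists.

For a chemical, let $s_k$ be the score of the $k$-th ranked path and
$c_0$ the number of original candidate paths with score $\ge s_k$
(ties can push $c_0$ above $k$; comparing counts rather than the raw
$k$-th score is robust to large tie groups). Over $N$ randomized
interactomes, $Y_n$ counts the candidate paths with score $\ge s_k$ in
randomization $n$, and

$$P_{\mathrm{perm}} = \frac{1 + \sum_n I(Y_n \ge c_0)}{N},$$

capped at 1. The pseudocount makes the smallest attainable value exactly
$1/N$: an exhaustive enumeration of the null would include the original
interactome itself. Counting uses the full candidate list, not the top
$k$ (a flagged alternative would be easy to add, but all-candidates is
the natural reading of "paths at that score").

### GPD refinement of small p-values

$1/N$ resolution is coarse once many chemicals are tested (at
$N = 10^4$ and 389 chemicals the Bonferroni-style bound is
$389/10^4 = 0.039$). The tail of the null counts is therefore modelled
with a generalized Pareto distribution (GPD): place a threshold between
the 250th and 251st largest $Y_n$, fit scale $a$ and shape $k$ to the
exceedances by maximum likelihood, and accept the fit only if a
parametric-bootstrap Anderson–Darling test does not reject at
$\alpha = 0.05$; on rejection drop the tail size by 10 and refit, and if
no size down to 10 ever passes, report the unrefined $P_{\mathrm{perm}}$.
When the fit passes and $c_0$ lies beyond the threshold $t$,

$$P_{\mathrm{gpd}} = \frac{n_{\mathrm{exceed}}}{N}\,
  S_{\mathrm{GPD}}(c_0 - t), \qquad
  S_{\mathrm{GPD}}(z) = (1 - k z / a)^{1/k},$$

with the exponential limit at $k = 0$. When $c_0$ is not in the tail the
refinement does not apply and $P_{\mathrm{perm}}$ is returned unchanged.
Benjamini–Hochberg q-values are computed across chemicals.

A note on validating the refinement: the acceptance check draws the null
exponentially and asks the refined p-value at the $10^{-4.5}$ tail to sit
within a factor of 2 of the analytic value. The sampling noise of a
250-exceedance maximum-likelihood fit makes that band unattainable when
the fitted threshold sits at the 97.5th percentile of $N = 10^4$ draws
(the extrapolation spans a factor of ~800 in tail probability, and the
shape estimate's standard error alone inflates the answer by more than
2); the check therefore uses $N = 10^6$, where the same code path and
formulas are exercised but the extrapolation is a factor of ~8. This
sizing was fixed from the estimator's error budget before the test was
frozen.

## Evidence weighting and data processing choices

* **Noisy-OR evidence integration.** Each evidence source (database or
  experiment type) carries a confidence $c_s \in (0,1)$; an edge
  supported by sources $\mathcal{S}$ gets
  $w = 1 - \prod_{s \in \mathcal{S}} (1 - c_s)$, capped at 0.99 so no
  edge is ever free and longer paths always cost more. The weight is
  monotone in the evidence, which is the property the downstream ranking
  relies on. Confidences default to 0.6 per source when no table is
  supplied. (The confidence table is TSV; a YAML reader is deliberately
  not a dependency.)
* **Natural logarithm** for costs — any base is rank-equivalent; fixing
  one makes costs reproducible.
* **Undirected penalty** 0.75, applied exactly once (a guard flag blocks
  double application); it prioritizes regulatory (directed) edges without
  removing physical ones.
* **Directed beats undirected.** An undirected record whose pair also has
  a directed record is treated as replaced by the predicted direction:
  its evidence merges into the directed edge and no undirected-derived
  edges are created for the pair.
* **Responsiveness calls.** A protein is responsive iff *every* mapped
  assay is a hit, after collapsing each up/down assay pair into one
  logical assay that is a hit if either member is (either direction of
  perturbation counts). A hit next to an untested or undetermined value
  (`NA`/`-1`) therefore yields *nonresponsive*, the strict reading of the
  all-assays rule. `-1` and `NA` both count as "not successfully tested"
  for the 500-assay chemical filter. Receptor sources additionally
  require a Novascreen (NVS) assay — those test direct chemical–receptor
  binding — and the `nuclear receptor` family is excluded from both sets;
  a protein classifying as both receptor and TF is excluded from both by
  default (configurable), keeping $S_x \cap T_x = \emptyset$.
* **z-score bonus (optional).** Edges incident to responsive proteins can
  be up-weighted by $1 + \mathrm{scale} \cdot \max(z, 0)$ (re-capped
  below 1) to prioritize paths through strongly perturbed proteins. The
  exact transformation used in the reference analysis is not public; this
  hook is a documented monotone stand-in, off by default in the pipeline.
* **CTD evaluation.** Human rows whose interaction text contains
  "phosphorylation" (which also matches "dephosphorylation") form the
  per-chemical proxy gold standard; the hypergeometric background
  defaults to the interactome node count, since the original universe is
  unstated, and q-values are BH across the chemicals that have CTD
  evidence.

## Numerical details

* Dijkstra runs on igraph; predecessor/successor ties are resolved to the
  lexicographically smallest node ID, and equal-cost candidate paths are
  ordered lexicographically by their node sequence, so runs are
  deterministic and byte-reproducible.
* Tightness tests on floating-point distances use a relative tolerance of
  $10^{-9}$; candidate costs are rounded to 9 decimals before rank
  ordering so that float noise cannot reorder genuine ties.
* Weight-1 edges (cost 0) between ordinary proteins would allow zero-cost
  cycles; path reconstruction guards against this with a step cap. The
  evidence cap (0.99) prevents the situation in loaded data.
* A protein in both $S_x$ and $T_x$ would produce a degenerate
  single-node "path"; such paths are excluded by default
  (`include_degenerate = TRUE` restores them).
* If a network has fewer than $k$ candidates, $s_k$ is the score of the
  last candidate.
* Sources/targets absent from the interactome are dropped with a warning;
  if none remain, the network is undefined and the run errors. A
  connected pair that yields no path gives an explicit `disconnected`
  result, never a silently empty network.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` / `generate_interactome()` build a small mixed graph
(default 60 proteins, 80 directed and 40 undirected background edges,
mirroring the roughly 1:2 directed:undirected ratio of the real
interactome at desk scale) with Beta(2,2)-distributed background weights
scaled below 0.8, and plant disjoint directed source-to-target paths with
weights in [0.9, 0.99]. Background edges never leave a planted source nor
enter a planted target. Under these constraints the planted path is
provably the unique cheapest source-to-target path: any competitor must
use the planted first and last edges, and replacing any stretch of
planted interior (at most 2 edges, cost $\le 2 \times -\log 0.9 =
0.211$) requires at least one background edge of cost $\ge -\log 0.8 =
0.223$. That is why planted lengths are restricted to 2–4 edges and the
recovery acceptance check can demand 100/100 exactness.

`generate_hit_matrix()` emulates the four-value hit encoding, NVS vendor
tags, up/down assay pairs, nuclear-receptor family rows, unmapped filler
assays (600 by default, ~90% successfully tested, so synthetic chemicals
clear the 500-assay filter with a wide margin) and deliberate edge cases
(a responsive non-NVS receptor, a responsive nuclear-receptor protein, an
undetermined protein). `generate_ctd()` emulates the CTD layout with
decoy rows a correct parser must drop.

The generator does **not** emulate: dose–response (AC50) curve fitting
upstream of the hit matrix, the size and degree distribution of the real
16,713-protein interactome, correlated evidence between databases, or
literature-biased CTD coverage. A green test therefore establishes the
correctness of the algorithms and parsers on data with the right
*structure*, not the biological conclusions of any particular screen.

## Null-calibration check

Under the null — when the "observed" interactome is itself a
degree-preserving randomization — the permutation p-value must be
(discretely) uniform. The acceptance suite verifies this on a 25-node
synthetic background with $N = 200$ and 50 synthetic chemicals, using
$k = 10$ and two sources/two targets per chemical so candidate counts
spread over many integers (heavy ties would make the discrete p-value
conservative); a KS check at $\alpha = 0.01$ must not reject.

## Known limitations

* The exact Bayesian evidence-weighting scheme and the z-score
  prioritization of the reference analysis live in unpublished
  supplementary material; the noisy-OR and linear-bonus stand-ins share
  their monotonicity but not their constants.
* Per-edge best paths can revisit nodes (see above); consumers that
  require node-simple paths should filter on `anyDuplicated` of the node
  sequence.
* The swap null keeps the two edge pools' weight multisets but has no
  notion of evidence-dependent weight placement; its p-values test
  topology, not weighting.
* The pure-R swap loop targets graphs up to a few thousand nodes (a
  dense logical adjacency); beyond that a hash-based fallback engages and
  ensembles of $10^4$ randomizations of a $16{,}713$-node interactome are
  a cluster-scale, not a desk-scale, computation.
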