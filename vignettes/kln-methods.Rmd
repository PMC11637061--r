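---
title: "Ranking influential nodes by neighborhood KL divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking influential nodes by neighborhood KL divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(klnrank)
```

## The problem

In an undirected contact or communication network, which nodes matter most?
A practical reading of "matter" is *damage*: if this node fails (is removed,
quarantined, vaccinated), how badly is information or disease flow through
its neighborhood disrupted?  klnrank scores every node by simulating exactly
that removal and measuring, in information-theoretic terms, how far the
neighborhood's dissemination probabilities are pushed from their intact
state.  The resulting KLN score combines that local entropy loss with two
classical structural attributes — degree (a local property) and K-shell
depth (a global one) — and finally credits each node with the damage
potential of its whole one-hop neighborhood.

## The model

Write $G = (V, E)$ for a simple undirected graph, $\Gamma(i)$ for the
neighbors of $i$, $d(i)$ for degree and $\mathrm{Kshell}(i)$ for the k-core
index.  For a candidate node $i$:

**Real distribution.** While $i$ is intact, its neighbors exchange
information through it; the chance that the flow favors neighbor $j$ is
taken proportional to $j$'s degree:
$$p_i(j) = \frac{d(j)}{\sum_{j \in \Gamma(i)} d(j)}.$$

**Fitting distribution.** Remove $i$ and its edges.  Each neighbor $n$ now
faces a changed world, summarized by one probability row over the neighbors
$j$ (including $n$ itself):
$$\chi_{in}(j) = \frac{\sqrt{\lambda(n,j)}\, d'(j)}
                      {\sum_{j \in \Gamma(i)} \sqrt{\lambda(n,j)}\, d'(j)},$$
where $d'(j)$ is $j$'s degree after the removal and $\lambda(n,j)$ is the
*path change factor*: the reciprocal of the post-removal shortest distance
between $n$ and $j$, set to $1/2$ when no path remains (the pair formerly
communicated through $i$ in two hops), and to $1$ on the self term.

**Entropy loss and scores.** Each row is compared against the real
distribution with the Kullback–Leibler divergence
$D'_{ij} = \sum_x p_i(x) \log_{10} \frac{p_i(x)}{\chi_{ij}(x)}$, weighted by
the neighbor's K-shell and summed:
$D_i = \sum_{j\in\Gamma(i)} \mathrm{Kshell}(j)\, D'_{ij}$.  The *damage
influence* adds degree, $DE(i) = D_i + d(i)$, and the final importance
aggregates the one-hop neighborhood:
$$\mathrm{KLN}(i) = DE(i) + \sqrt{\textstyle\sum_{j \in \Gamma(i)} DE(j)}.$$

`kln_rank()` computes all of this for every node, reusing each $DE$ across
the neighborhood sums, and orders nodes by KLN descending.

```{r}
g <- worked_example_graph()
head(kln_rank(g), 5)
```

## Parameters that matter

* **`log_base` (default 10).**  The divergence definition leaves the
  logarithm base free; the base only rescales $D_i$ relative to the degree
  term in $DE(i)$, so it *does* affect rankings.  We fix base 10 because the
  packaged worked example's per-neighbor divergences (0.042, 0.031, 0.002,
  0.013) recompute exactly in base 10 and in no other common base (natural
  logs give values roughly 2.3-fold larger).  The validator
  `validate_worked_example()` locks this in.
* **`floor` (default `1e-10`).**  A neighbor that was a leaf hanging off the
  removed node has post-removal degree 0, which would zero a whole fitting
  column and make the divergence infinite.  Replacing the zero by a tiny
  positive floor keeps every row a valid distribution while preserving the
  intended reading — losing your only link is maximal damage — as a large
  but finite loss.  The floor is configurable; results are insensitive to
  its exact magnitude because it enters only through $\log(\cdot)$.
* **`cutoff` (default off).**  Exact post-removal distances require a BFS
  from each neighbor.  An optional hop cutoff treats farther pairs as
  unreachable ($\lambda = 1/2$) and *only* them — an explicit approximation
  flag for very large graphs, never silently applied.
* **SIR `alpha`, `beta` (defaults 0.1 and 1).**  Per-contact infection and
  per-round recovery probabilities of the spreading oracle.  With
  `beta = 1` every infected node transmits for exactly one round, which is
  the standard setting for capacity experiments; `alpha` around 0.01–0.1
  keeps outbreaks informative (larger values infect everything regardless
  of the seed, washing out node differences).
* **`iterations` (default 1000).**  Monte-Carlo replicates behind each
  capacity estimate; standard errors are carried in the outputs.
* **Tier `boundaries` (default 30, 183, 248, 382).**  The rank cut points
  of the epidemic-management case study: primary through quaternary
  management groups, then ordinary nodes.

## Numerical and convention choices

* **Self term.** Each fitting row includes its owner with $\lambda = 1$ and
  the owner's post-removal degree.  This follows the worked example's
  arithmetic; excluding the self term instead would renormalize every row
  and change all divergences.
* **K-shell values are always taken from the intact graph**, computed once
  per ranking.  Re-decomposing after each removal would both be quadratic
  and disagree with the worked example's weights.
* **Ties** in any ranking break by ascending node identifier (bytewise), so
  every ordering is deterministic and platform-independent.
* **Node identifiers are opaque strings**; `"01"` and `"1"` are different
  nodes.  This prevents silent merging when real edge lists mix padded and
  unpadded labels.
* **Unreachable is `Inf`**, an explicit sentinel, never a large finite
  stand-in that could leak into arithmetic.
* **Isolated nodes** carry $DE = \mathrm{KLN} = 0$, shell 0, degree
  centrality 0, and teleport-only PageRank mass.
* **Eigenvector centrality** iterates on $A + I$ from a uniform start: the
  shift makes the dominant eigenvalue strictly largest in modulus, so the
  iteration also converges on bipartite graphs, where plain power iteration
  oscillates with period 2.
* **Kendall tau** follows the pair-count definition literally: tied pairs
  join neither the concordant nor the discordant count, while the
  denominator stays at $n(n-1)/2$.  Identical score vectors containing ties
  therefore correlate at slightly below 1 — a property of the definition,
  not a bug; a `tau_b` variant with the usual tie correction is available.
* **SIR update order** is infect-then-recover within a synchronous round;
  with recover-first, `beta = 1` experiments could never spread at all.
  Draw order within a round is fixed, so a seed fully determines a
  trajectory, and replicate $k$ always uses seed `rng_seed + k`, making
  node-versus-node comparisons paired and replicate counts extensible.

## The worked-example fixture

The package ships a small synthetic network
(`inst/extdata/toy_network_synthetic.txt`, 13 nodes, 18 edges) built so
that every published quantity of the reference walkthrough's node-1
neighborhood recomputes exactly: the real distribution
$(0.385, 0.231, 0.154, 0.231)$, all four fitting rows, the per-neighbor
divergences, $D_1 = 0.218$ and $DE(1) = 4.218$.  The original example
figure was never published in machine-readable form (and is described with
one more node than any recoverable realization), so the fixture pins the
printed quantities — which are what the algorithm's correctness rests on —
rather than a node count, and `validate_worked_example()` re-checks all of
them at run time.  One arithmetic wrinkle is documented rather than
reproduced: the walkthrough's final importance value for node 1 is printed
as 7.826, but its own printed components give
$4.218 + \sqrt{12.959} = 7.818$; the package reproduces the arithmetic, not
the misprint.

## What the generators emulate — and what they do not

Property tests and simulations run on Erdős–Rényi, Barabási–Albert
(triangle-seeded, so a graph with $n$ nodes has exactly $3 + (n-3)m$
edges) and Watts–Strogatz graphs from `random_graph()`.  These cover sparse
homogeneous, heavy-tailed and clustered-ring regimes, which is enough to
exercise every code path (leaves, disconnections, ties, automorphic pairs).
They do not emulate the community structure, degree correlations or
temporal aggregation of real contact networks, so green tests certify the
*implementation* — score definitions, invariances, oracle agreement — not
any claim about how well KLN ranks nodes on a particular empirical network.

## Verification strategy and problem sizes

Every pipeline stage has an independent oracle in the test suite: a
Floyd–Warshall all-pairs check for BFS distances, literal iterative
stripping for K-shell, a dense eigen-decomposition and a direct linear
solve for the eigenvector and PageRank baselines, a naive-loop
reimplementation of the full KLN pipeline (agreement to `1e-9`), an
exhaustive outcome-tree enumeration for SIR expectations, and a quadratic
pair scan for Kendall tau.  Scale choices keep the default run fast while
covering the regimes of interest: oracle graphs up to 25–30 nodes, 1000
random neighborhoods for distribution validity, Kendall vectors up to
$n = 200$, and 20,000 SIR replicates on the triangle benchmark (chosen so
that three Monte-Carlo standard errors is a tight band around the exact
2.25 expectation).

## Known limitations

* Exact post-removal distances make worst-case cost higher than the ideal
  $O(\langle k\rangle^2 n)$ of cheap distance lookups; the `cutoff` flag is
  the provided trade-off.
* Weighted or directed semantics are out of scope throughout; directed GML
  input is symmetrized on read.
* Baseline eigenvector/PageRank parameterizations are standard-parameter
  references; results on published benchmark tables that never stated their
  parameters are not reproductions.
* `spreading_capacity()` is a per-node Monte-Carlo loop; for networks
  beyond a few thousand nodes, reduce `iterations` or parallelize
  externally.
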