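---
title: "Link Partitioning Around Medoids: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Link Partitioning Around Medoids: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpam)
```

## The problem and the model

Community detection in networks — protein interaction maps, gene co-expression
graphs, social and ecological networks — usually partitions *nodes*. Many real
communities overlap: a node can sit at the interface of two functional
modules. LPAM (Link Partitioning Around Medoids) obtains overlapping node
communities from a *disjoint* clustering of the *edges*. The intuition is that
relations, not actors, define communities: an edge usually belongs to exactly
one social context, while a node participates in as many contexts as its
edges do.

Given an unweighted, undirected, connected simple graph $G = (V, E)$ with $n$
nodes and $m$ edges, and a requested number of communities $k$:

1. **Line graph.** Build $L(G)$: one vertex per edge of $G$, two vertices
   adjacent iff the edges share an endpoint. A disjoint clustering of
   $V(L(G))$ is an edge partition of $G$.
2. **Distance matrix.** Compute a pairwise distance matrix $D$ on $V(L(G))$
   using either the *commute distance*
   $d_{cm}(i,j) = \mathrm{vol}(G)\, d_r(i,j)$, where $d_r$ is the effective
   resistance and $\mathrm{vol}$ the sum of degrees, or the *amplified
   commute distance*
   $$d_{amp}(i,j) = d_r(i,j) - \tfrac{1}{d_i} - \tfrac{1}{d_j}
     + \tfrac{2 a_{ij}}{d_i d_j},$$
   which removes the degree-dominated terms that swamp the commute distance
   on large graphs ($a_{ij}$ is the 0/1 adjacency indicator; the self-weight
   terms of the general formula vanish on simple graphs).
3. **k-median.** Choose $k$ medoid vertices $S$ of $L(G)$ minimizing
   $\sum_{j} \min_{c \in S} d_{jc}$ — the classic NP-hard p-median /
   facility-location problem — and assign every edge to its nearest medoid.
4. **Belonging coefficients and cover.** For node $i$ and cluster $c$, the
   belonging coefficient $F_{ic}$ is the fraction of $i$'s incident edges in
   cluster $c$; node $i$ joins community $c$ iff $F_{ic} \ge \theta$.

Assumptions worth stating: the graph must be **simple, unweighted and
connected** (resistance across components is infinite, and edge weights are
discarded by the line-graph construction, so weighted input is rejected
rather than silently altered); and $k$ is an input, not something the method
estimates.

## Distance ties and overlapping membership

The nearest-medoid indicator is defined with a weak inequality: an edge
whose distance to several medoids is minimal belongs to *all* of them. On
generic graphs exact ties never occur and every row of the belonging matrix
sums to 1. On highly symmetric graphs ties are structural and meaningful:
on the $8{\times}8$ lattice with $k=2$ the eight boundary edges are exactly
equidistant to both medoids, and only because they count toward both
clusters do the two halves share a band of nodes. `run_lpam()` therefore
detects ties with a relative tolerance of $10^{-9}$ and lets tied edges
contribute to every nearest cluster (so row sums may exceed 1 on symmetric
graphs), while the exported `belonging_fractions()` keeps the plain
single-assignment semantics (rows sum to exactly 1) for edge labelings
produced elsewhere.

## Tunable parameters

* **`k`** (positive integer, required): number of communities, bounded by
  $m$.
* **`distance`** (`"cm"` default, or `"acm"`): commute vs amplified commute
  distance on the line graph. They often agree on small graphs; the
  amplified variant is preferable as graphs grow, because raw commute
  distance degenerates toward a function of the endpoint degrees.
* **`theta`** (default 0.5, dimensionless in $[0,1]$): the belonging
  threshold. Inclusive comparison, so a node with an exact $0.5/0.5$ split
  joins both communities. Raising $\theta$ never adds a membership: large
  $\theta$ pushes nodes into a single community (or into `unassigned`),
  small $\theta$ into many. 0.5 is the default because in most annotated
  networks few nodes straddle more than two communities. Overlap driven by
  a *single* incident edge (e.g. a degree-4 lattice node with one edge in a
  neighbouring cluster) only becomes visible at $\theta \le 1/d_i$ — on the
  regular lattice the textbook overlapping picture appears at
  $\theta = 0.25$, not at 0.5, where the cover is the disjoint quadrant
  partition.
* **`solver`** (`"exact"` default, or `"clarans"`): see below.
* **`tol`** ($10^{-9}$): relative eigenvalue cutoff for the Laplacian
  pseudoinverse.
* **`budget`** ($10^7$): cap on the number of candidate medoid sets the
  exact enumeration may visit.
* **`numlocal`** (4) and **`maxneighbor`**
  ($\max(250, \lceil 0.0125\,k(m-k)\rceil)$): CLARANS restart count and
  neighbour-sampling patience, following the original CLARANS
  recommendations.

Nodes reaching $\theta$ in no cluster are reported in `unassigned` rather
than force-assigned; covers are allowed to leave nodes out.

## Numerical choices

* **Resistance via pseudoinverse.** The Kirchhoff minor-ratio definition of
  effective resistance is numerically awkward ($O(n^5)$ determinants); the
  implementation uses the symmetric eigendecomposition of the Laplacian once
  per graph ($O(n^3)$) and treats eigenvalues below `tol` times the largest
  as zero. The minor-ratio form survives as an independent test oracle, and
  Foster's theorem ($\sum_{(i,j) \in E} d_r(i,j) = n-1$) is checked as a
  second, formula-independent probe.
* **Exact solver.** No integer-programming backend is assumed. Global
  optimality is certified by lexicographic enumeration of $k$-subsets in
  C++ with two admissible prunings: a deterministic greedy upper bound and
  the per-point lower bound $\sum_i \min(\text{cur}_i, \text{suffmin}_i(c))$,
  which is non-decreasing in the candidate index and lets whole sibling
  ranges be skipped. Among equal-objective optima (relative tolerance
  $10^{-9}$) the lexicographically smallest medoid tuple is returned, which
  pins down results on symmetric graphs where the optimum is a large orbit.
  Instances with $\binom{m}{k}$ beyond `budget` are refused explicitly
  rather than silently falling back to a heuristic.
* **CLARANS.** Randomized single-swap local search, first-improvement, with
  `maxneighbor` consecutive failures declaring a local optimum and
  `numlocal` restarts. All randomness flows from one user seed through R's
  RNG; the caller's RNG state is saved and restored. Equal-objective
  restarts resolve to the lexicographically smaller medoid set.
* **Negative distances.** The amplified commute distance can be zero or
  slightly negative for distinct vertices on small graphs (on the 3-path,
  the endpoints' amplified distance is exactly 0). Values are deliberately
  not clamped, and both solvers accept them; the objective stays well
  defined.
* **Determinism.** Node labels are opaque strings; all orderings
  (edge canonical form, line-graph vertex order, tie-breaks) use
  locale-independent byte order, so results are identical across platforms
  and `LC_COLLATE` settings.

## Evaluation metrics

`onmi()` implements overlapping normalized mutual information with each
community as a binary variable over the universe, the standard validity
constraint on the $2{\times}2$ joint entropies, and two normalizations: the
per-community-averaged LFK variant (default) and the max-normalized variant
$I/\max(H(A),H(B))$. The two are not comparable with each other. On the
bundled karate-club fixture ($k=2$, commute distance, exact solver,
$\theta = 0.45$) the max-normalized variant reproduces the reference value
0.91796 exactly, which is how the external reference tooling evidently
normalized. `omega_index()` is the chance-corrected agreement of pairwise
co-membership multiplicities, and `f1_best_match()` the symmetrized
best-match F1. Each metric is verified against a literal-formula oracle on
enumerated small covers.

`cover_stats()` reports the average internal degree
$\langle 2 m_S / n_S\rangle$ and the normalized cut
$\langle \mathrm{cut}(S)/\mathrm{vol}(S) +
\mathrm{cut}(S)/(\mathrm{vol}(G)-\mathrm{vol}(S))\rangle$; a community with
zero or full volume contributes a zero cut term and is logged. Internal edge
density and modularity-density variants are deliberately not offered:
standard formulas do not reproduce the reference values for them, so they
are out of the conformance surface.

## Synthetic generators and what they do (not) show

`grid_graph()` builds the deterministic $r \times c$ lattice (no community
structure, zero clustering coefficient) used as the pedagogical example.
`planted_partition(l, g, p_in, p_out)` and `sbm_graph(sizes, probs)` draw
independent Bernoulli edges per node pair — the classic planted-partition /
stochastic-block models with block ground truth. Per-pair sampling (not
fixed edge counts) is used, and identical seeds replay bit-identical graphs.

The recovery benchmark used in the tests is PP($l=4$, $g=8$,
$p_{in}=0.9$, $p_{out}=0.05$): 32 nodes, ~110 edges, strong assortative
structure. With the exact solver, $k=4$, $\theta=0.5$, the median ONMI
against ground truth over 20 seeds is 1.0. The rare draw whose graph is
disconnected is resampled deterministically (seed offset) since the method
requires one metric space. These generators emulate block-structured random
graphs only: degree heterogeneity, triangles beyond chance, genuinely
overlapping ground truth, and weighted edges are all absent, so passing
recovery tests here does not certify performance on real heavy-tailed or
hierarchical networks.

Problem sizes throughout the suite were chosen to keep the exact solver in
its enumeration regime (line graphs around 100–120 vertices at $k \le 4$,
about $10^6$–$10^7$ candidate sets, roughly a second each): large enough to
exercise the full pipeline, small enough that optimality is certified rather
than approximated.

## Known limitations

* Exact solving is exponential in $k$: beyond `budget` candidate sets the
  method refuses; use CLARANS there, which carries no optimality guarantee
  (on random instances with $m \le 15$ it attains the optimum in well over
  90% of seeded runs).
* Commute distance loses discriminative power on large graphs; prefer
  `"acm"` beyond a few hundred edges.
* Weighted, directed graphs and multigraphs are out of scope by
  construction; so are alternative generators (LFR-style benchmarks) and
  wrappers around other community-detection methods.
* $k$ must be chosen by the user; the objective decreases monotonically in
  $k$, so it cannot itself select $k$.
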