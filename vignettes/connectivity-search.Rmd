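---
title: "Metapath connectivity search: models and methods"
author: "hetpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metapath connectivity search: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetpath)
```

# The problem

A hetnet (heterogeneous information network) is a graph whose nodes and
edges carry types: genes, compounds, diseases, pathways, connected by
typed relations such as *binds*, *treats* or *participates*.  Given two
nodes -- say a disease and a pathway -- a natural question is *how* they
are related: along which type-level route (metapath) is their connectivity
larger than the degrees of the two nodes alone would predict, and which
individual paths carry that connectivity?  `hetpath` answers this without
any training labels, by comparing an observed connectivity score against a
degree-conditioned permutation null.

# Connectivity score: the degree-weighted path count

For a metapath $m$ (a composable sequence of metaedges) the path count
between a source node $s$ and target node $t$ is the number of *simple*
paths from $s$ to $t$ that follow $m$'s types.  Paths through hub nodes
are ubiquitous and rarely informative, so each path is weighted by its
**path degree product**

$$\mathrm{PDP} = \prod_{(i,j) \in \text{path}} (d_i\, d_j)^{-w},$$

where $d_i$ and $d_j$ are the endpoint degrees *of that edge's metaedge
type* and $w \ge 0$ is the damping exponent.  The **DWPC** is the sum of
PDPs over all simple paths.  With $w = 0$ the DWPC is the raw path count.
The package default is $w = 0.5$ (square-root damping); $w = 0.4$ has
also been used for gene-disease prediction and is supported everywhere
via the `w` argument.

## Computing DWPCs by matrix multiplication

Let $D(XyZ)$ be the degree-weighted biadjacency matrix of metaedge $XyZ$,
with entries $A_{ij}(d_i d_j)^{-w}$ (defined as 0 where $A_{ij} = 0$, so
zero degrees never produce division by zero).  The product of the $D$
matrices along a metapath counts *walks*; to count *paths* the repeated
metanodes must be corrected:

* **Short repeats** ($X \ldots X$, and $X \ldots X \ldots X$): subtract
  the diagonal of the (segment) product.  For three occurrences the two
  inner segments are corrected first; only the diagonal -- walks returning
  to the start node -- remains to subtract, so the correction is exact.
* **Nested repeats** ($X a Y b Y c X$): correct the inner $Y$ repeat, form
  the triple product, subtract its diagonal.
* **Overlapping repeats** ($X a Y b X c Y$): inclusion-exclusion over the
  two collisions $x_1 = x_3$ and $y_2 = y_4$, using two diagonal-scaled
  products and one Hadamard term (`dwpcOverlapping`).

`dwpc()` segments a metapath hierarchically (`segmentMetapath`): repeats of
different metanodes whose position intervals do not overlap are corrected
independently and multiplied (disjoint groups); overlapping intervals form
a group handled by the rules above, recursively.  Metanodes occurring once
need no treatment and are folded into the adjacent products.  Whatever
falls outside these rules -- a metanode repeated four or more times, or
interleavings like $ABCABC$ and $ABABA$ -- is a *complex* segment and is
computed exactly by depth-first simple-path enumeration (compiled; also
exposed as `method = "enumeration"`, which serves as the independent
reference implementation for the whole metapath).  Because segmentation
confines every repeated metanode to a single segment, multiplying segment
results is exact.

`method = "approximate"` corrects simple patterns exactly but only the
first repeat inside complex segments.  Since it removes a subset of the
invalid walks and all weights are non-negative, it bounds the exact DWPC
from above; results are flagged `approximate`.

Segment DWPCs are cached per store, keyed by sub-metapath abbreviation and
$w$, with least-recently-used eviction (`options(hetpath.cacheSize =)`).
Caching is semantically invisible -- the test suite asserts equality with
the cache disabled.

# The permutation null

Observed DWPCs have no analytic null, so the package builds one from
XSwap-permuted networks: repeatedly pick two edges $(a,b), (c,d)$ and
rewire to $(a,d), (c,b)$, rejecting swaps that create self-loops or
duplicate edges.  Degrees of every node are preserved exactly; edge
*meaning* is destroyed.  Each metaedge is permuted independently, with
its swap stream seeded by a stable hash of (seed, metaedge abbreviation),
so adding a metaedge never reshuffles the others.  The attempt count is
`multiplier` (default 10) times the edge count; the default follows common
practice for XSwap-style randomization and is exposed as an argument
rather than asserted as canonical.  Undirected same-metanode edge sets are
permuted as unordered pairs and mirrored back into a symmetric matrix.
Stored edge orientation is preserved during swapping (the classic XSwap
chain); this makes degenerate fixtures exactly analyzable -- a star can
never swap, two disjoint edges can only toggle between the two matchings
-- at the cost of not being fully ergodic over all degree-preserving
graphs, a known property of plain XSwap.

## Degree grouping

Because permutation preserves only degree, permuted DWPCs for all node
pairs sharing a (source degree, target degree) pair -- degrees taken with
respect to the metapath's first and last metaedge -- are exchangeable.
Pooling them multiplies the effective number of permutations, most where
it is needed most (low-degree pairs, which produce the most zero DWPCs).
Per (metapath, source degree, target degree) the package keeps five
additive running totals: the number of null DWPCs ($N$), the number of
nonzero ones ($n$), their sum, their sum of squares, and the number of
permuted hetnets.  `mergeNullStats` is an exact fieldwise sum, so
statistics accumulate incrementally and in any order.  Grouping is always
within a metapath, never across metapaths.

## The gamma-hurdle null distribution

Nonzero null DWPCs within a degree group are well approximated by a gamma
distribution, while a sizable fraction of nulls is exactly zero.  The null
is therefore modeled as a hurdle: $P(X = 0) = 1 - \lambda$ and
$X \mid X > 0 \sim \Gamma(\alpha, \beta)$.  Parameters come from the
method of moments on the running totals, with Bessel's correction for the
second moment:

$$\hat\lambda = n/N, \quad \hat\mu = \tfrac{\sum x}{n}, \quad
\hat\sigma^2 = \tfrac{n \sum x^2 - (\sum x)^2}{n(n-1)}, \quad
\hat\alpha = \hat\mu^2/\hat\sigma^2, \quad \hat\beta = \hat\mu/\hat\sigma^2.$$

The tail probability of an observed DWPC $t$ is

$$p = P(X \ge t) = \begin{cases} 1 & t = 0\\
\lambda\, Q(\alpha, \beta t) & t > 0,\end{cases}$$

with $Q$ the regularized upper incomplete gamma function
(`stats::pgamma(..., lower.tail = FALSE)`).  The $\lambda$ factor is a
deliberate design choice: under the hurdle model the zero mass never
exceeds a positive threshold, so the tail beyond any $t > 0$ must be
carried by the gamma component scaled by $\lambda$; omitting the factor
would make $P(X \ge t) \to \lambda^{-1} \cdot$ its limit as $t \to 0^+$
inconsistent with $P(X = 0) = 1 - \lambda$.

The gamma part requires $n \ge 2$ and $\hat\sigma^2 > 0$ (the variance
threshold uses a relative epsilon of `.Machine$double.eps` times
$\hat\mu^2$ to absorb round-off in the running totals).  Otherwise
`dwpcPvalue` falls back to three empirical rules evaluable from the
summaries alone: $t = 0 \Rightarrow p = 1$; all nulls zero and
$t > 0 \Rightarrow p = 0$; all nonzero nulls equal to one value
$v \Rightarrow p = 0$ if $t > v$, else $n/N$.  No monotone transform is
applied to DWPCs before comparison: tail probabilities are invariant under
monotone transforms, so raw DWPCs are compared to raw null DWPCs.

## Multiple testing

A search evaluates every metapath between two metanodes, so raw p-values
are Bonferroni-adjusted by the number of metapaths of the same length
between the source and target metanode (under the package's
reverse-deduplicated enumeration convention), capped at 1.  The cap is
standard practice rather than part of the published procedure.  A false
discovery rate procedure is deliberately not offered: FDR methods want all
p-values at once and a uniform null under no signal, and most DWPCs are
zero.

# Ranking results

`connectivitySearch` sorts metapath rows by adjusted p-value, breaking
ties by DWPC descending and then abbreviation (the tie-breaks are an
implementation choice for determinism).  For reported metapaths it
enumerates the individual simple paths; each path's
`percent_of_dwpc` is its PDP divided by the DWPC, and its
**path score** is `percent_of_dwpc * -log10(p)` using the metapath's raw
p-value by default (`pathScoreAdjusted = TRUE` switches to the adjusted
one).  An empirical $p = 0$ is capped at $-\log_{10} p = 320$, near the
smallest positive double, to keep scores finite.  The database-storage
rule is modeled as an output filter (`applyStorageFilter`): length-1
metapaths keep all nonzero DWPCs (a direct edge is always worth showing),
longer metapaths keep rows with adjusted $p \le 5 (n_s n_t)^{-0.3}$,
penalizing metapaths between plentiful metanodes.

# Storage format

A hetnet lives in a directory: `metagraph.json` (the schema),
`nodes/<Metanode>.tsv` (position, identifier, name; identifiers sorted
lexicographically so matrix indices are reproducible), and one matrix file
per metaedge under `edges/` -- MatrixMarket `.mtx` when density is below
0.7, dense TSV otherwise.  The threshold rule is strictly "sparse when
density < 0.7".  Gzip/bzip2/xz (and zip for matrices) compression is
recognized on read by extension.  Matrices load lazily on first access.
Path counts are stored in doubles carrying exact integer values (exact up
to $2^{53}$, far beyond any fixture here); DWPCs are 64-bit floats.

# Synthetic data

`makeFixture` generates deterministic hetnets from a spec: per-metanode
node counts and per-metaedge density, edge count, explicit edges, or exact
degree sequences (realized greedily and then XSwap-shuffled; exactness of
the degrees is asserted in tests).  Edges are uniform draws without
replacement from the allowed pair set, with no self-loops or duplicates.
What these fixtures emulate is the *structure* the method depends on:
typed sparse biadjacency, heterogeneous degrees, symmetric same-metanode
relations.  What they do not emulate: real networks' heavy-tailed degree
distributions, degree correlations, clustering, and the biological
redundancy between metaedge types.  Passing tests therefore demonstrate
correctness of the algorithms and calibration of the null machinery under
the stated generative conditions, not biological validity of any
particular ranking on real data.

The bundled Hetionet v1.0 metagraph (11 metanodes, 24 metaedges, only
gene-regulates-gene directed) is used for schema-level checks -- metapath
enumeration counts and storage thresholds -- which need no node or edge
data.

# Numerical choices and problem sizes

* All DWPC comparisons in tests use an absolute tolerance of `1e-10`;
  observed agreement between the matrix and enumeration routes is at the
  `1e-16` level.  Tiny negative round-off (> `-1e-12`) from the
  inclusion-exclusion subtractions is clipped to zero.
* Path enumeration is budgeted (default `1e8` edge extensions for
  `dwpc`, `1e7` for per-pair path listing); exceeding the budget raises a
  classed resource error naming the budget rather than running away.
* Canonical metapath orientation is the lexicographically smaller (byte
  order) of the abbreviation and its reverse; palindromes are their own
  reverse.  This makes reverse-deduplication deterministic and
  locale-independent.
* The calibration experiment in the test suite uses a 3-metanode chain
  (60 nodes each, density 0.15), one length-2 metapath, 50 permutations
  with one held out, yielding roughly 2,700 nonzero held-out DWPCs; the
  Kolmogorov-Smirnov distance of the conditional tail probabilities from
  uniform is about 0.05-0.07.  The oracle-equivalence suite runs 100
  random metagraphs (2-4 metanodes, 6-14 nodes each, 2-4 metaedges) over
  all metapaths up to length 4 at $w \in \{0, 0.4, 0.5\}$.  These sizes
  were chosen so the whole suite runs in a few minutes while every code
  path (all repeat patterns, both matrix formats, directed and undirected
  same-metanode metaedges) is exercised.
* Degenerate inputs are defined, not special-cased away: edgeless stores
  yield zero matrices and $p = 1$ rows; isolated nodes have degree 0 and
  never enter damping factors; a single-edge or star edge list is
  invariant under XSwap.

# Known limitations

* Complex repeat patterns fall back to exhaustive enumeration, which can
  be expensive on dense stores; the budget makes the failure mode explicit.
  The precise boundary of which long patterns are segmentable is an
  implementation choice -- anything the hierarchical rules cannot prove
  safe goes to enumeration, which is exact but slower.
* Plain XSwap is not fully ergodic for undirected edge sets (orientation
  is preserved during swapping), and the swap-attempt multiplier is a
  convention, not an estimated mixing time.
* The gamma-hurdle is a working approximation; for degree groups with few
  nonzero nulls the empirical fallback is coarse (its support is
  $\{0, n/N, 1\}$).
* Bonferroni control is conservative by design; see the multiple-testing
  section.
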