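---
title: "Shared-gene enrichment networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared-gene enrichment networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbinet)
```

## The problem

Psychiatric disorders that co-occur clinically — the motivating case is
obsessive–compulsive disorder (OCD) and bipolar disorder (BD) — often
share genetic risk factors. A common integrative strategy starts from
two curated disorder gene lists, intersects them, asks which annotated
categories (KEGG-style pathways, GO molecular functions and cellular
components, brain-region expression sets) are over-represented among
the shared genes, and then assembles genes and significant categories
into one heterogeneous network whose central nodes are read as the core
of the shared biology. comorbinet implements that pipeline end to end,
offline, with every statistic computed in-package.

The curation itself — literature search, inclusion/exclusion screening,
identifier reconciliation against a genome browser — is upstream manual
work. The package takes the curated lists as plain-text inputs and
exposes an alias map (`read_alias_map()`) as the hook for
identifier-level deduplication, rather than re-implementing any lookup.

## Over-representation analysis

For a query list of $n$ genes inside a background universe of $N$
genes, and a category with $K$ members in the background, the overlap
$k$ under uniform sampling follows a hypergeometric distribution. The
enrichment p-value is the upper tail

$$P(X \ge k) \;=\; \sum_{i=k}^{\min(n,K)}
  \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

accumulated in log space (`lchoose` plus log-sum-exp), which is stable
for arbitrarily large backgrounds; naive factorials would overflow
around $N \approx 20$. Within each annotation collection the p-values
are adjusted by the Benjamini–Hochberg step-up
($\mathrm{adj}_{(i)} = \min_{j \ge i} \min(1, m\,p_{(j)}/j)$), and a
category is significant when its FDR is at or below the threshold and
it overlaps the query at all.

Choices a user should know about, with defaults:

* **Background** (`N`): a user-supplied universe file, or — default —
  the union of all members across the loaded collections. Web
  enrichment portals rarely document their reference set; the
  union-of-annotation choice is the one a reader can reproduce exactly
  from the inputs.
* **FDR threshold**: 0.05, the conventional portal default; every
  category entering the network passed it.
* **Category-size filter**: categories with fewer than 3 or more than
  500 in-background members are not tested (standard ORA practice;
  tiny categories are unstable, huge ones uninformative).
* **Multiple-testing scope**: BH runs *within* each collection, the
  way enrichment portals report each annotation database separately.
  Pooling across collections would be more conservative for the large
  collections and less for the small ones; per-collection matches how
  the case-study tables are organized (one FDR column per database).
* **Ordering**: results sort by p-value with lexicographic
  `category_id` tie-breaks, so output is deterministic even under
  heavy ties (e.g. duplicated member sets).

Brain-region sets deserve a note: the original analysis obtained them
from a specificity-thresholded expression tool whose internals (pSI
computation from expression panels) are not reproducible from text.
Here a region set is simply one more GMT collection run through the
same hypergeometric machinery; the bundled case-study region FDRs come
from the published table, not from re-computation.

## The heterogeneous network

Nodes are genes and significant categories; the edge $(g, c)$ exists
iff $c$ is significant and $g$ is in its query overlap. The graph is
undirected (membership has no direction) and bipartite across the
gene/category divide — the constructor enforces bipartiteness, no
self-loops, no parallel edges, and degree $\ge 1$ for every category
node. Genes with no significant membership are dropped by default
(`include_isolated_genes = FALSE`): in the case study only 34 of the
58 shared genes appear in the published network, consistent with
unannotated or non-significant genes having been excluded. The flag
exposes the alternative.

Exports are Cytoscape-ready: SIF (`gene TAB member_of TAB category`)
and GraphML with `node_type`, `display_name`, `fdr`, and optionally
the computed centralities as node attributes. Rebuilding from the same
inputs is byte-identical.

## Topology

`topology_report()` mirrors the NetworkAnalyzer-style summary: per-node
betweenness, closeness and degree; node, edge, and connected-component
counts; and the betweenness/degree histograms.

* **Betweenness** uses Brandes' algorithm over unweighted shortest
  paths, endpoints excluded, and is normalized by $(n-1)(n-2)/2$ over
  the *whole* graph (not per component), so values lie in $[0,1]$ and
  pairs in different components contribute nothing. The whole-graph
  convention matches the desktop network-analysis tools whose outputs
  this style of study tabulates; published per-node values from such
  tools are nevertheless not asserted anywhere, because their exact
  normalization is tool- and version-dependent. Graphs with fewer than
  three nodes get all-zero betweenness.
* **Closeness** uses the reachable-set correction
  $(r/\sum d)\cdot(r/(n-1))$, where $r$ is the number of nodes
  reachable from $v$: well-defined on disconnected graphs (a real
  possibility with isolated genes included); isolated nodes score 0.
* **Histograms**: betweenness bins are half-open $[a, a+w)$ with the
  final bin closed at 1 (default width 0.1, the resolution at which
  such studies describe their centrality distributions); degree counts
  run from 0 to the observed maximum. Counts always sum to the node
  count.
* **Ranking** is descending with node-id tie-breaks, optionally per
  node type, which makes the exported gene and category tables stable.

Brandes and the BFS-based closeness/component labeling are implemented
in the package; igraph serves only as an independent cross-check in the
test suite, alongside a brute-force geodesic-enumeration oracle on
small seeded graphs.

## The synthetic-study generator

`generate_study()` emits a complete, file-level study so every stage is
testable offline: a universe of synthetic symbols (`G000001`…), two
disorder lists with an *exact* intersection size (shared genes drawn
first, then disjoint remainders — counts are assertable, not merely
expected), and one GMT per collection with planted enriched categories.
Defaults mirror the motivating study's scale: universe 2000, lists 397
and 148 sharing 58, four collections (50 pathway, 50 molecular
function, 50 cellular component, 20 brain-region categories; sizes
uniform on 20–40) with 5/5/5/3 planted categories.

Planting: each planted category contains
$\lceil f \cdot |\text{shared}| \rceil$ shared genes ($f$ =
`planted_overlap_fraction`, default 0.5, i.e. 29 of 58); if a drawn
size is smaller than that, it is raised to it, which resolves the
tension between the 20–40 size range and a 29-gene planted core. A
designated hub gene (the first shared gene, recorded in
`manifest.json`) is a member of *every* category of every collection,
so it has maximal brokerage in the built network by construction — the
property the ranking tests rely on. With `planted_overlap_fraction =
0` nothing is planted and no hub is placed, giving pure null draws for
calibration studies. One RNG sub-stream per artifact (lists, each
collection) is derived from the master seed, so adding a collection
never perturbs the lists; the same seed always yields byte-identical
files.

Because the hub sits in every category, background (non-planted)
categories each carry one guaranteed query hit: their p-values are
slightly off-null. The recovery benchmarks therefore quote the
false-positive rate *among non-planted categories* (about 2% at
defaults) alongside the classic false-discovery proportion among
discoveries, which the one-hit shift inflates (about 13% at defaults —
a property of the construction, not of the BH implementation, which is
verified against an independent step-up).

What the generator does **not** emulate: GO's DAG structure, correlated
category memberships, pathway size distributions, or realistic
gene-symbol semantics. Passing recovery tests therefore demonstrates
the statistical machinery on independent random categories, not
performance on real, heavily overlapping annotation databases.

## The bundled case study

`ocd_bd_case_study()` ships the published node tables of the OCD–BD
network — 34 genes and 28 significant categories (7 pathways, 10
molecular functions, 8 cellular components, 3 brain regions) with
their reported FDR and betweenness values — and `ocd_bd_network()`
rebuilds the 62-node network from them. The original edge list was
never published, so membership is assigned deterministically (gene $i$
to category $i \bmod 28$); that suffices for node-count bookkeeping
but means edge-dependent quantities (edge count, recomputed
centralities) are placeholders, and the published per-node betweenness
values are carried for reference only.

## Numerical and testing choices

* Exact-arithmetic oracle for the hypergeometric tail: for $N \le 40$
  every binomial coefficient and partial sum fits exactly in a double
  (all $\le \binom{40}{20} \approx 1.4\times10^{11} \ll 2^{53}$), so a
  Pascal-triangle pmf summation is exact; the implementation matches
  it to $10^{-12}$ relative on the exhaustive grid, and matches the
  reference survival function on a dense lattice up to $N = 200$.
* Centrality oracles: Floyd–Warshall distances plus explicit
  enumeration of every geodesic, on 50 seeded bipartite graphs of at
  most 14 nodes — small enough for exhaustive enumeration, large
  enough to cover disconnected and multi-geodesic cases.
* Calibration: 2000 null queries of size 58 against 50 random
  categories in a 2000-gene universe; the $p \le 0.05$ rate stays
  below $0.05 + 3\,\mathrm{SE}$ (discreteness makes the
  hypergeometric tail conservative, so the observed rate is nearer
  2–3%).
* Recovery: 100 seeded default studies; all planted categories are
  recovered at FDR $\le 0.05$ and the hub tops the gene betweenness
  ranking in every seed.
* Problem sizes throughout (universe 2000, $\le 200$-point
  hypergeometric lattice, 14-node oracle graphs, 100-seed benchmark)
  were chosen so the whole suite runs in about a minute on a laptop
  while still exercising every code path at the study's own scale.

## Known limitations

* Published per-node centralities from desktop tools are not
  reproducible without their exact normalization and the unpublished
  edge list; the package reproduces structure and counts, not those
  decimals.
* ORA treats categories independently; overlapping real-world
  categories induce correlated tests that BH handles only in its usual
  conservative sense.
* The brain-region route is a plain gene-set analysis; it does not
  re-implement specificity-index thresholding of expression panels.
* The pipeline is symbol-based. Identifier hygiene is delegated to the
  alias map; a wrong or incomplete map silently becomes wrong input
  (the collapse counts in the log are the guard rail).
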