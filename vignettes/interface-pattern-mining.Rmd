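---
title: "Methods: mining conserved arrangements on protein–protein interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining conserved arrangements on protein–protein interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model implemented by `ppimine`, the numerical
and algorithmic choices behind it, and the scope and limitations of the
bundled synthetic generators. It states no empirical result that is not
recomputed by the package's test suite or its `scripts/acceptance.R`
script.

## The interface model

An interface is modeled as a labeled bipartite multigraph `G(P, I, E)`.
The two node sets are the heavy atoms of the two chain groups of a
complex; an edge is a typed non-covalent contact between atoms on opposite
sides. Nodes never join atoms on the same side, so all structure within a
chain is deliberately ignored: the object of study is the contact fabric
of the interface itself.

### Atom typing

Each atom is assigned a *set* of physicochemical roles — acceptor (`AC`),
aromatic (`AR`), donor (`DN`), hydrophobic (`HB`), negative (`NG`),
positive (`PS`) — from a typing table keyed on residue and atom name
(`default_typing_table()`). Ambivalent atoms keep all their roles: a
histidine imidazole nitrogen is simultaneously `AC/AR/DN/PS`, because the
ring is titratable near physiological pH and both tautomeric and
protonated forms occur in crystal structures. Label sets are serialized
canonically (sorted two-letter codes joined by `/`), so string equality on
serializations is set equality.

The table is a package choice, not an observable of the input data: users
with different protonation conventions can supply their own table to
`assign_atom_labels()`. Atoms absent from the table are excluded with a
warning rather than guessed at.

### Contacts

A cross-side atom pair forms an edge of a given type when the endpoint
labels satisfy the type's condition *and* the Euclidean distance lies in
the type's closed window (Å):

| type | condition | window |
|---|---|---|
| aromatic stacking | both aromatic | 1.5–3.5 |
| hydrogen bond | one acceptor, one donor | 2.0–3.0 |
| hydrophobic | both hydrophobic | 2.0–3.8 |
| repulsive | like charges | 2.0–6.0 |
| salt bridge | unlike charges | 2.0–6.0 |

Both window ends are inclusive; the test suite probes every window at
`min − ε`, `min`, the midpoint, `max` and `max + ε`. One pair may carry
several parallel edges: an `AC/NG` carboxylate oxygen 2.8 Å from a `DN/PS`
guanidinium nitrogen is both a hydrogen bond and a salt bridge, and the
multigraph keeps both. The windows are geometric screening criteria over
atom centers — no angular terms, no energy model — and can be overridden
per type via `contact_criteria()`.

### Label pruning

After edges are computed, each node's label set is *pruned* to the union,
over its incident edges, of the roles that edge type actually exercises
against that partner. An acceptor/negative oxygen whose only contact is a
salt bridge is retained as `NG` alone: its acceptor role never
materialized on this interface. Pruning is what later allows a pattern
node to match a graph node with a *richer* label set (subset
compatibility) without losing specificity.

Atoms with no edge are dropped, and each connected component of the pruned
multigraph becomes one dataset graph; components are ordered by their
smallest atom id so the decomposition is deterministic.

## Features and clustering

### Counting matrix

Each dataset graph is encoded as a row of *pair-label* counts: every
unordered node pair joined by at least one edge contributes exactly one
count to the column named by the canonical serializations of its two
endpoint label sets, sorted and joined by `-` (e.g. `AC/NG-DN`). Edge
multiplicity is intentionally ignored — adjacency, not bond count, is the
feature — and columns are sorted lexicographically over the label
alphabet observed in the dataset.

### Truncated SVD

The counting matrix is factorized by an *uncentered* SVD and reduced to
`Θ = U_d Σ_d`. Uncentered, because the rows are sparse non-negative counts
whose origin is meaningful (the zero vector is "no contacts at all");
centering would destroy that and is not needed for a distance-based
clustering. The rank `d` is the smallest one whose leading squared
singular values retain at least a threshold (default 95%) of the total —
`select_rank()` — and the test suite checks this choice against an
independent eigendecomposition of `XᵀX`.

### Spectral clustering

Clustering operates on the rows of `Θ`:

* **Similarity graph.** A k-nearest-neighbor graph with *union*
  symmetrization (an edge when either endpoint lists the other among its
  `k` nearest rows) and binary weights by default. `k` is chosen as the
  smallest value of `max(1, round(p·r))`, with `p` swept from 1% to 90% in
  1% steps, whose graph is connected (`select_k()`): a disconnected
  similarity graph would pre-impose its components as clusters.
  A Gaussian kernel (`weights = "gaussian"`) is available and is useful
  when equal-size tight groups force the first connected `k` to bridge
  them; with binary weights such bridges can misplace individual boundary
  points, which is a property of the method, not of the implementation.
* **Cluster count.** The number of clusters `n` is the index in
  `[2, n_max]` at which the gap between consecutive ascending eigenvalues
  of the normalized symmetric Laplacian `I − D^{-1/2} A D^{-1/2}` is
  largest, ties resolved toward the smaller `n` (`eigen_gap()`). On a
  graph with `m` exact connected components the zero eigenvalue has
  multiplicity `m` and the heuristic returns `m`.
* **Partition.** Rows are embedded into the `n` eigenvectors of the
  smallest eigenvalues, row-normalized to unit length, and partitioned by
  k-means seeded from a configured seed with multiple restarts
  (`spectral_cluster()`), so a fixed seed yields a fixed partition.
* **Joint selection.** `select_parameters()` evaluates every rank at or
  above the variance threshold, records the per-rank `(k, n)` table, and
  selects the minimal `k`, then the modal `n` among ties, then the
  smallest such `d`; the full table is returned so the selection can be
  audited (`plot_parameter_selection()`).

## Mining

Inside a cluster, the interface multigraphs are collapsed to labeled
simple graphs — parallel typed edges become one edge labeled by the sorted
types joined with `/` — and mined with gSpan:

* Patterns are connected subgraphs with at least one edge; node and edge
  labels are compared by exact string equality during mining.
* Support is transaction-based: the number of distinct graphs containing
  the pattern, with threshold `ceiling(min_support · |D|)`. Multiple
  embeddings in one graph count once.
* Canonicality uses minimum DFS codes with rightmost-path extension:
  backward edges only from the rightmost vertex, forward edges only from
  rightmost-path vertices, and a candidate code is pruned unless it equals
  the greedily constructed minimum code of the pattern it encodes
  (`min_dfs_code()`). The test suite checks the miner's full output —
  patterns *and* supports — against exhaustive connected-subgraph
  enumeration with VF2 isomorphism grouping on dozens of seeded random
  datasets.
* `filter_maximal()` reduces the result to the antichain of patterns not
  contained in any other mined pattern; `support_sweep()` tabulates
  pattern counts across a support grid, since a final support threshold is
  a judgment call between pattern frequency and pattern size that the
  package leaves to its configuration.

## Mapping patterns back to atoms

A mined pattern is not necessarily a vertex-induced subgraph of its
occurrence graphs, so mapping matches *line graphs*: `L(pattern)` is
matched into `L(graph)` by VF2-style backtracking, where two line nodes
are compatible when their edge labels and their endpoint label pairs are
compatible under the subset rule (`labels_compatible()`: one label set
contains the other). On the pattern side, node labels are first restricted
to the roles the pattern's own edges exercise (`derive_display_labels()`),
mirroring the pruning applied to graphs.

Because non-isomorphic graphs can share a line graph (the K3 / K1,3
ambiguity), every line-graph match is back-translated into a node map and
re-verified edge by edge on the original graphs — injectivity, adjacency
and label compatibility — before being reported; mappings are then
deduplicated by node-map image. The test suite checks the mapper against a
brute-force injective-embedding search, including the K3 / K1,3 cases,
which must produce zero verified mappings.

## Evaluation

`reference_set()` holds literature-derived items: *residue rules* (residue
name and author number, optionally restricted to one interface side) and
*micro-structure rules* (small labeled graphs that must be
subgraph-compatible with the pattern under the subset rule). A pattern is
relevant when it matches at least one item; per-group precision is the
relevant fraction of the group's patterns, recall the fraction of items
matched, and the pooled row aggregates all groups. Ratios are rounded to
two decimals. The arithmetic — including the 9-relevant-of-13 case, which
pools to a precision of 0.69 with recall 1.00 — is fixed by unit tests.

## Synthetic generators: scope and limits

The package is validated without external structural data, using two
generators whose outputs are checked at generation time:

* `generate_complex_fixture()` writes a toy two-chain PDB text with each
  requested contact planted as an isolated atom pair at an exact distance,
  plus decoy atoms far outside every window. Atom and residue names come
  from the real typing table, so labeling is exercised authentically, but
  the geometry is a jittered lattice with **no physical plausibility**: no
  covalent structure, no sterics, single atoms standing in for residues.
  The generator re-derives each planted pair's implied interaction types
  from the criteria and aborts on any disagreement, so a fixture that
  generates at all is guaranteed to produce exactly its planted edges.
* `generate_graph_dataset()` produces connected labeled graphs with a
  motif embedded verbatim in an exact fraction of them; noise nodes and
  edges are rejection-sampled so no accidental extra motif copy arises
  anywhere (verified with the exact-label containment matcher). Its
  purpose is ground truth for miner and mapper tests, not realism.

Problem sizes in the tests (graphs of up to a few dozen nodes, datasets of
up to a dozen graphs for oracle comparisons) are chosen so that the
independent brute-force oracles remain exhaustive within the suite's time
budget; the algorithms themselves have no such limits, but gSpan's
worst-case cost is exponential in pattern size, and dense low-diversity
label alphabets will make any frequent-subgraph miner struggle.

## Other deliberate choices

* All randomness (k-means restarts, fixture jitter, dataset sampling)
  flows from explicit seeds; reruns with the same configuration are
  byte-identical at the artifact level.
* Cluster ids are relabeled by first appearance and 0-based, so they are
  stable across platforms independent of k-means' internal numbering.
* The pipeline persists every stage (GraphML + JSON node-link graphs, CSV
  matrices and assignments, JSON patterns and mappings), and each stage
  function reads only the previous stage's files, so single stages can be
  re-run and audited in isolation.

## Limitations

* Contact detection is purely distance-and-label based; hydrogen-bond
  geometry, ring orientation in stacking, and solvent exposure are out of
  scope.
* The typing table covers the 20 standard residues' heavy atoms; modified
  residues, ligands, nucleic acids and waters are excluded.
* Mining compares labels exactly; near-synonymous label sets (e.g. `AC`
  vs `AC/DN`) are distinct patterns at mining time and only unify at
  mapping time through subset compatibility.
* The eigen-gap heuristic assumes the similarity structure has a dominant
  block organization; on featureless data it will still return some `n`,
  and the per-rank report should be inspected rather than trusted blindly.
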