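# ppimine

Mining conserved structural arrangements on protein–protein interfaces.

`ppimine` models the interface of a protein complex as a labeled bipartite
multigraph of atomic contacts, groups similar interfaces by spectral
clustering of a pair-label counting matrix, mines frequent labeled subgraphs
inside each group with a gSpan implementation based on minimum DFS codes, and
maps the mined patterns back to concrete atoms so they can be inspected and
scored against literature-derived reference residues.

## The model

1. **Atom typing.** Every heavy atom of the two chain groups is assigned a
   set of physicochemical roles: hydrogen-bond acceptor (`AC`), aromatic
   (`AR`), donor (`DN`), hydrophobic (`HB`), negative (`NG`), positive
   (`PS`). A label set is serialized canonically as sorted codes joined by
   `/` (an aspartate carboxylate oxygen is `AC/NG`).
2. **Contacts.** A cross-chain atom pair forms a typed edge when its labels
   satisfy the interaction's condition and its distance lies in a closed
   window (Å): aromatic stacking 1.5–3.5, hydrogen bond 2.0–3.0, hydrophobic
   2.0–3.8, repulsive and salt bridge 2.0–6.0. One pair may carry several
   parallel edges (an `AC/NG` oxygen at 2.8 Å from a `DN/PS` nitrogen is
   both a hydrogen bond and a salt bridge).
3. **Pruning.** A node keeps only the labels at least one incident edge
   actually exercises: an acceptor/negative oxygen whose only contact is a
   salt bridge is retained as negative only. Connected components of the
   pruned multigraph are the dataset graphs.
4. **Counting matrix and SVD.** Each graph becomes a row counting, for every
   adjacent node pair, the pair-label of its endpoints (edge multiplicity
   does not inflate the count). The uncentered matrix is reduced by
   truncated SVD to the smallest rank retaining 95% of the variance.
5. **Spectral clustering.** A symmetrized k-nearest-neighbor graph is built
   over the reduced rows, with the smallest `k` (swept over 1%–90% of the
   row count) that connects it; the number of clusters is picked by the
   largest gap in the ascending normalized-Laplacian spectrum, and the rows
   are partitioned by seeded k-means in the spectral embedding.
6. **Mining.** Per cluster, the multigraphs are collapsed to simple graphs
   (parallel edge types joined as `hydrogen_bond/salt_bridge`) and every
   connected subgraph reaching the minimum support is enumerated by gSpan;
   non-maximal patterns can be filtered out.
7. **Mapping.** Patterns are located in their occurrence graphs by matching
   line graphs (so patterns need not be vertex-induced), with subset-label
   compatibility — a pattern node displayed as `NG` matches a graph node
   labeled `AC/NG`. Every line-graph match is re-verified on the original
   graphs, which discards the K3 / K1,3 artifacts of line-graph isomorphism.
8. **Evaluation.** Mined patterns are scored for precision and recall
   against a reference set of residue rules and micro-structure rules.

## Worked example

The package ships deterministic fixture generators, so the whole pipeline
can be exercised without any external data. Plant three contacts in a toy
two-chain complex and recover them:

```r
library(ppimine)

planted <- data.frame(
  res_p  = c("ASP", "SER", "LEU"),
  atom_p = c("OD1", "OG", "CD1"),
  res_i  = c("ARG", "THR", "VAL"),
  atom_i = c("NH1", "OG1", "CG1"),
  type   = c("salt_bridge", "hydrogen_bond", "hydrophobic"),
  distance = c(4.5, 2.8, 3.5)
)
fx <- generate_complex_fixture(planted, seed = 1, complex_id = "demo")
pdb_path <- tempfile(fileext = ".pdb")
writeLines(fx$pdb, pdb_path)

atoms <- assign_atom_labels(
  read_interface_atoms(pdb_path, list(P = "A", I = "B"), complex_id = "demo")
)
dataset <- build_graph_dataset(atoms)
dataset
#> # A tibble: 3 × 6
#>   graph_id complex_id component n_nodes n_edges graph
#>      <int> <chr>          <int>   <int>   <int> <list>
#> 1        0 demo               0       2       1 <intrfc_g>
#> 2        1 demo               1       2       1 <intrfc_g>
#> 3        2 demo               2       2       1 <intrfc_g>
```

Each planted pocket became one dataset graph; labels are pruned to the
roles the contact exercises (the `AC/NG` aspartate oxygen is retained as
`NG` because its only edge is a salt bridge):

```r
to_simple_graph(dataset$graph[[1]])$nodes[, c("id", "label", "resname", "atom", "side")]
#> # A tibble: 2 × 5
#>      id label resname atom  side
#>   <int> <chr> <chr>   <chr> <chr>
#> 1     1 PS    ARG     NH1   I
#> 2     8 NG    ASP     OD1   P

build_counting_matrix(dataset)
#> # A tibble: 3 × 4
#>   graph_id `AC/DN-AC/DN` `HB-HB` `NG-PS`
#>   <chr>            <int>   <int>   <int>
#> 1 0                    0       0       1
#> 2 1                    1       0       0
#> 3 2                    0       1       0
```

Mine frequent patterns and map one back onto its atoms:

```r
graphs <- setNames(lapply(dataset$graph, to_simple_graph), dataset$graph_id)
pats <- filter_maximal(gspan(graphs, min_support = 1/3))
pats[, c("pattern_id", "dfs_code", "n_edges", "support_count", "support_fraction")]
#> # A tibble: 3 × 5
#>   pattern_id dfs_code                     n_edges support_count support_fraction
#>        <int> <chr>                          <int>         <int>            <dbl>
#> 1          0 (0,1,AC/DN,hydrogen_bond,AC…       1             1            0.333
#> 2          1 (0,1,HB,hydrophobic,HB)            1             1            0.333
#> 3          2 (0,1,NG,salt_bridge,PS)            1             1            0.333

maps <- map_all(pats[1, ], graphs)
maps$node_map[[1]][, c("pattern_node", "target_resname", "target_resno", "target_atom", "target_side")]
#> # A tibble: 2 × 5
#>   pattern_node target_resname target_resno target_atom target_side
#>          <int> <chr>                 <int> <chr>       <chr>
#> 1            1 THR                       2 OG1         I
#> 2            2 SER                       2 OG          P
```

The full pipeline (graphs → features → cluster → mine → map → evaluate) is
available as composable stage functions (`run_pipeline()`, `stage_*()`) and
as a thin command-line wrapper in `inst/scripts/ppimine`, each stage reading
the previous stage's persisted artifacts.

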