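# Shared synthetic complexes used by the interface-graph, io and pipeline
# tests. Each planted pair sits in an isolated pocket, so every pair becomes
# one connected component of the interface graph.

fixture_planted_a <- function() {
  data.frame(
    res_p = c("ASP", "SER", "LEU"),
    atom_p = c("OD1", "OG", "CD1"),
    res_i = c("ARG", "THR", "VAL"),
    atom_i = c("NH1", "OG1", "CG1"),
    type = c("salt_bridge", "hydrogen_bond", "hydrophobic"),
    distance = c(4.5, 2.8, 3.5)
  )
}

fixture_planted_b <- function() {
  data.frame(
    res_p = c("PHE", "GLU"),
    atom_p = c("CZ", "OE1"),
    res_i = c("PHE", "ASP"),
    atom_i = c("CZ", "OD2"),
    type = c("aromatic_stacking", "repulsive"),
    distance = c(1.8, 5.0)
  )
}

# writes two fixture PDB files plus a reference YAML; returns a pipeline
# config list rooted at `dir`
fixture_pipeline_config <- function(dir, seed = 0) {
  fa <- generate_complex_fixture(fixture_planted_a(), seed = 1, complex_id = "cplxA")
  fb <- generate_complex_fixture(fixture_planted_b(), seed = 2, complex_id = "cplxB")
  pa <- file.path(dir, "cplxA.pdb")
  pb <- file.path(dir, "cplxB.pdb")
  writeLines(fa$pdb, pa)
  writeLines(fb$pdb, pb)
  ref <- file.path(dir, "reference.yaml")
  writeLines(c(
    "- id: saltbridge-asp",
    "  residue:",
    "    resname: ASP",
    "    resno: 1"
  ), ref)
  list(
    complexes = list(
      list(path = pa, chains = list(P = "A", I = "B"), id = "cplxA"),
      list(path = pb, chains = list(P = "A", I = "B"), id = "cplxB")
    ),
    output = file.path(dir, "out"),
    reference = ref,
    min_support = 0.5,
    seed = seed
  )
}
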