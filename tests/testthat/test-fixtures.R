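test_that("complex fixtures are deterministic text and self-validating", {
  fx1 <- generate_complex_fixture(fixture_planted_a(), seed = 5)
  fx2 <- generate_complex_fixture(fixture_planted_a(), seed = 5)
  expect_identical(fx1$pdb, fx2$pdb)
  fx3 <- generate_complex_fixture(fixture_planted_a(), seed = 6)
  expect_false(identical(fx1$pdb, fx3$pdb)) # decoy jitter moves
  expect_true(all(nchar(fx1$pdb[startsWith(fx1$pdb, "ATOM")]) >= 66))
  expect_equal(nrow(fx1$manifest$planted), 3)
})

test_that("a fixture whose planted types disagree with the criteria is rejected", {
  bad <- data.frame(
    res_p = "ASP", atom_p = "OD1", res_i = "ARG", atom_i = "NH1",
    # 2.8 A implies hydrogen bond AND salt bridge, not just a salt bridge
    type = "salt_bridge", distance = 2.8
  )
  expect_error(generate_complex_fixture(bad), "implies types")
  # and a distance outside every window cannot be planted as an edge
  far <- data.frame(
    res_p = "LEU", atom_p = "CD1", res_i = "VAL", atom_i = "CG1",
    type = "hydrophobic", distance = 10
  )
  expect_error(generate_complex_fixture(far), "implies types")
})

test_that("near-miss pairs are validated to produce no edge", {
  nm <- data.frame(
    res_p = c("SER", "SER"), atom_p = "OG", res_i = c("THR", "THR"),
    atom_i = "OG1", type = c("hydrogen_bond", ""),
    distance = c(2.8, 3.2), near_miss = c(FALSE, TRUE)
  )
  fx <- generate_complex_fixture(nm)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fx$pdb, path)
  atoms <- assign_atom_labels(
    read_interface_atoms(path, list(P = "A", I = "B"))
  )
  edges <- compute_contacts(atoms)
  expect_equal(nrow(edges), 1) # only the genuine pair forms an edge
  expect_equal(edges$type, "hydrogen_bond")
})

test_that("decoy atoms stay far outside every contact window", {
  fx <- generate_complex_fixture(fixture_planted_a(), n_decoys = 6)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fx$pdb, path)
  atoms <- assign_atom_labels(
    read_interface_atoms(path, list(P = "A", I = "B"))
  )
  p <- atoms[atoms$side == "P", ]
  i <- atoms[atoms$side == "I", ]
  d <- sqrt(outer(p$x, i$x, "-")^2 + outer(p$y, i$y, "-")^2 +
    outer(p$z, i$z, "-")^2)
  # exactly the planted pairs are within the widest window
  expect_equal(sum(d <= max(contact_criteria()$max)), 3)
})

test_that("graph datasets plant the motif in exactly the requested graphs", {
  motif <- make_simple_graph(
    tibble::tibble(id = 1:3, label = c("NG", "PS", "NG")),
    tibble::tibble(from = c(1, 2), to = c(2, 3), label = "salt_bridge")
  )
  ds <- generate_graph_dataset(
    motif,
    n_graphs = 10, planted_fraction = 0.6, seed = 9,
    node_labels = c("AC", "DN", "HB"),
    edge_labels = c("hydrogen_bond", "hydrophobic")
  )
  expect_length(ds$graphs, 10)
  expect_length(ds$manifest$planted_ids, 6)
  for (gid in names(ds$graphs)) {
    has <- sg_contains(ds$graphs[[gid]], motif, "exact")
    expect_equal(has, gid %in% ds$manifest$planted_ids)
  }
  # all graphs are connected simple graphs
  expect_true(all(vapply(
    ds$graphs, function(g) nrow(g$edges) >= nrow(g$nodes) - 1, logical(1)
  )))
})

test_that("graph dataset generation is reproducible and validates inputs", {
  motif <- make_simple_graph(
    tibble::tibble(id = 1:2, label = c("NG", "PS")),
    tibble::tibble(from = 1, to = 2, label = "salt_bridge")
  )
  a <- generate_graph_dataset(motif, 6, 0.5, seed = 3)
  b <- generate_graph_dataset(motif, 6, 0.5, seed = 3)
  expect_identical(
    lapply(a$graphs, function(g) g$edges),
    lapply(b$graphs, function(g) g$edges)
  )
  expect_error(generate_graph_dataset(motif, 10, 0.25), "integer")
  disconnected <- make_simple_graph(
    tibble::tibble(id = 1:3, label = c("NG", "PS", "HB")),
    tibble::tibble(from = 1, to = 2, label = "salt_bridge")
  )
  expect_error(generate_graph_dataset(disconnected, 4, 0.5), "connected")
})
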