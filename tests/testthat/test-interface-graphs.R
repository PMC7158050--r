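fixture_atoms <- function(planted = fixture_planted_a(), seed = 1) {
  fx <- generate_complex_fixture(planted, seed = seed, complex_id = "cplx")
  path <- withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame())
  writeLines(fx$pdb, path)
  atoms <- read_interface_atoms(path, list(P = "A", I = "B"), complex_id = "cplx")
  assign_atom_labels(atoms)
}

test_that("PDB parsing keeps coordinates, sides and provenance", {
  atoms <- fixture_atoms()
  expect_setequal(unique(atoms$side), c("P", "I"))
  expect_true(all(atoms$chain[atoms$side == "P"] == "A"))
  expect_equal(sum(atoms$resname == "ASP" & atoms$atom == "OD1"), 1)
  # planted salt bridge distance survives the round trip
  p <- atoms[atoms$resname == "ASP" & atoms$atom == "OD1", ]
  i <- atoms[atoms$resname == "ARG" & atoms$atom == "NH1", ]
  d <- sqrt((p$x - i$x)^2 + (p$y - i$y)^2 + (p$z - i$z)^2)
  expect_equal(d, 4.5, tolerance = 1e-3)
})

test_that("missing chains raise an error naming the available ones", {
  fx <- generate_complex_fixture(fixture_planted_a())
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fx$pdb, path)
  expect_error(
    read_interface_atoms(path, list(P = "A", I = "Z")),
    "available"
  )
  expect_error(read_interface_atoms(path, list(P = "A", I = "A")), "disjoint")
})

test_that("interface graph recovers exactly the planted contacts", {
  atoms <- fixture_atoms()
  edges <- compute_contacts(atoms)
  expect_equal(nrow(edges), 3)
  expect_setequal(edges$type, c("salt_bridge", "hydrogen_bond", "hydrophobic"))
  g <- build_interface_graph(atoms, edges)
  expect_equal(nrow(g$nodes), 6) # decoys never enter the graph
  expect_s3_class(g, "interface_graph")
})

test_that("node labels are pruned to the roles their edges exercise", {
  atoms <- fixture_atoms()
  g <- build_interface_graph(atoms, compute_contacts(atoms))
  ret <- function(res, atom) {
    g$nodes$retained[g$nodes$resname == res & g$nodes$atom == atom]
  }
  # ASP OD1 is typed AC/NG but its only edge is a salt bridge: keep NG
  expect_equal(ret("ASP", "OD1"), "NG")
  expect_equal(ret("ARG", "NH1"), "PS")
  # SER OG vs THR OG1 hydrogen bond works in both orientations: keep AC/DN
  expect_equal(ret("SER", "OG"), "AC/DN")
  expect_equal(ret("THR", "OG1"), "AC/DN")
  expect_equal(ret("LEU", "CD1"), "HB")
})

test_that("components split isolated pockets deterministically", {
  atoms <- fixture_atoms()
  g <- build_interface_graph(atoms, compute_contacts(atoms))
  comps <- extract_components(g)
  expect_length(comps, 3)
  # ordered by smallest atom id, so the planting order is preserved
  first_atoms <- vapply(
    comps, function(cg) min(cg$nodes$atom_id), numeric(1)
  )
  expect_equal(first_atoms, sort(first_atoms))
  expect_true(all(vapply(
    comps, function(cg) nrow(cg$nodes) == 2 && nrow(cg$edges) == 1, logical(1)
  )))
})

test_that("parallel typed edges collapse into a slash-joined simple edge", {
  planted <- data.frame(
    res_p = "ASP", atom_p = "OD1", res_i = "ARG", atom_i = "NH1",
    type = "hydrogen_bond/salt_bridge", distance = 2.8
  )
  atoms <- fixture_atoms(planted)
  g <- build_interface_graph(atoms, compute_contacts(atoms))
  sg <- to_simple_graph(g)
  expect_equal(nrow(sg$edges), 1)
  expect_equal(sg$edges$label, "hydrogen_bond/salt_bridge")
  # both roles are exercised, so the full label sets are retained
  expect_setequal(sg$nodes$label, c("AC/NG", "DN/PS"))
})

test_that("build_graph_dataset assembles components across complexes", {
  fa <- generate_complex_fixture(fixture_planted_a(), seed = 1, complex_id = "ca")
  fb <- generate_complex_fixture(fixture_planted_b(), seed = 2, complex_id = "cb")
  read_one <- function(fx, cid) {
    path <- withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame())
    writeLines(fx$pdb, path)
    assign_atom_labels(
      read_interface_atoms(path, list(P = "A", I = "B"), complex_id = cid)
    )
  }
  dataset <- build_graph_dataset(list(read_one(fa, "ca"), read_one(fb, "cb")))
  expect_equal(nrow(dataset), 5)
  expect_equal(dataset$graph_id, 0:4)
  expect_equal(unique(dataset$complex_id), c("ca", "cb"))
  expect_true(all(dataset$n_edges == 1))
})

test_that("simple graph construction rejects malformed input", {
  nodes <- tibble::tibble(id = 1:2, label = c("A", "B"))
  expect_error(
    make_simple_graph(nodes, tibble::tibble(from = 1, to = 1, label = "x")),
    "self-loop"
  )
  expect_error(
    make_simple_graph(
      nodes,
      tibble::tibble(from = c(1, 2), to = c(2, 1), label = "x")
    ),
    "parallel"
  )
  expect_error(
    make_simple_graph(nodes, tibble::tibble(from = 1, to = 3, label = "x")),
    "endpoint"
  )
})
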