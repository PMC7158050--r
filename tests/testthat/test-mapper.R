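k3 <- function(label = "AC") {
  make_simple_graph(
    nodes = tibble::tibble(id = 1:3, label = label),
    edges = tibble::tibble(
      from = c(1, 1, 2), to = c(2, 3, 3), label = "hydrogen_bond"
    )
  )
}

k13 <- function(label = "AC") {
  make_simple_graph(
    nodes = tibble::tibble(id = 1:4, label = label),
    edges = tibble::tibble(
      from = c(1, 1, 1), to = c(2, 3, 4), label = "hydrogen_bond"
    )
  )
}

test_that("line graph has one node per edge and adjacency by shared ends", {
  lg <- line_graph(k3())
  expect_equal(nrow(lg$nodes), 3)
  expect_equal(nrow(lg$edges), 3) # L(K3) = K3
  lg2 <- line_graph(k13())
  expect_equal(nrow(lg2$nodes), 3)
  expect_equal(nrow(lg2$edges), 3) # L(K1,3) = K3 too (Whitney)
  expect_error(
    line_graph(make_simple_graph(
      tibble::tibble(id = 1, label = "AC"),
      tibble::tibble(from = integer(0), to = integer(0), label = character(0))
    )),
    "edge"
  )
})

test_that("verification rejects the K3 / K1,3 line-graph artifact", {
  # K3 and K1,3 have isomorphic line graphs; after verification on the
  # original graphs, K3 must not map into K1,3 or vice versa
  expect_equal(nrow(map_pattern(k3(), k13())), 0)
  expect_equal(nrow(map_pattern(k13(), k3())), 0)
  # while the genuine automorphic mappings survive
  expect_equal(nrow(map_pattern(k3(), k3())), 6)
})

test_that("pattern mappings equal the brute-force embedding oracle", {
  set.seed(41)
  node_labs <- c("AC", "DN", "AC/NG", "DN/PS", "HB")
  edge_labs <- c("hydrogen_bond", "salt_bridge", "hydrophobic")
  for (trial in 1:15) {
    target <- random_labeled_graph(sample(5:7, 1), sample(1:3, 1), node_labs, edge_labs)
    pat <- random_labeled_graph(sample(2:3, 1), sample(0:1, 1), node_labs, edge_labs)
    got <- mapping_signatures(map_pattern(pat, target), pat)
    # oracle works on the same display-label view of the pattern
    patd <- pat
    patd$nodes$label <- suppressWarnings(derive_display_labels(pat))
    want <- oracle_embeddings(patd, target)
    expect_identical(got, want)
  }
})

test_that("subset labels let pruned pattern nodes match richer graph nodes", {
  # pattern: NG -salt- PS (as displayed after pruning); target nodes carry
  # the full AC/NG and DN/PS label sets
  pat <- make_simple_graph(
    tibble::tibble(id = 1:2, label = c("AC/NG", "DN/PS")),
    tibble::tibble(from = 1, to = 2, label = "salt_bridge")
  )
  target <- make_simple_graph(
    tibble::tibble(id = 10:11, label = c("AC/NG", "DN/PS")),
    tibble::tibble(from = 10, to = 11, label = "hydrogen_bond/salt_bridge")
  )
  expect_equal(derive_display_labels(pat), c("NG", "PS"))
  m <- map_pattern(pat, target)
  expect_equal(nrow(m), 1)
  expect_equal(sort(m$node_map[[1]]$target_id), c(10L, 11L))
  # a target with the wrong charge signs does not match
  bad <- make_simple_graph(
    tibble::tibble(id = 10:11, label = c("AC/NG", "AC/NG")),
    tibble::tibble(from = 10, to = 11, label = "salt_bridge")
  )
  expect_equal(nrow(map_pattern(pat, bad)), 0)
})

test_that("map_all covers every claimed occurrence and errors otherwise", {
  gs <- list(
    a = k3(), b = k3()
  )
  pats <- gspan(gs, 1.0)
  maps <- map_all(pats, gs)
  claimed <- sum(lengths(pats$occurrences))
  expect_setequal(unique(maps$graph_id), c("a", "b"))
  expect_true(nrow(maps) >= claimed)
  # a forged occurrence triggers the consistency error
  forged <- pats[1, ]
  forged$occurrences <- list(c("a", "zzz"))
  expect_error(map_all(forged, gs), "not present")
})

test_that("pattern_residues unions residues across mappings", {
  atoms <- tibble::tibble(
    atom_id = 1:2, side = c("P", "I"), label = c("AC/NG", "DN/PS"),
    x = c(0, 4.5), y = 0, z = 0,
    complex_id = "c1", chain = c("A", "B"),
    resname = c("ASP", "ARG"), resno = c(7L, 33L), insert = "",
    atom = c("OD1", "NH1")
  )
  g <- to_simple_graph(
    build_interface_graph(atoms, compute_contacts(atoms))
  )
  pat <- make_simple_graph(
    tibble::tibble(id = 1:2, label = c("NG", "PS")),
    tibble::tibble(from = 1, to = 2, label = "salt_bridge")
  )
  pats <- tibble::tibble(
    pattern_id = 0L, occurrences = list("g0"), graph = list(pat)
  )
  res <- pattern_residues(map_all(pats, list(g0 = g)))
  expect_equal(nrow(res), 2)
  expect_setequal(res$resname, c("ASP", "ARG"))
  expect_setequal(res$resno, c(7L, 33L))
})
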