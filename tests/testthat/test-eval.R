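test_that("reference sets accept residue and micro-structure items", {
  ref <- reference_set(
    list(id = "II", residue = list(resname = "ASP", resno = 189)),
    list(id = "IV", motif = make_simple_graph(
      tibble::tibble(id = 1:3, label = c("DN", "DN", "AC")),
      tibble::tibble(from = c(1, 2), to = c(3, 3), label = "hydrogen_bond")
    ))
  )
  expect_equal(ref$type, c("residue", "motif"))
  expect_equal(ref$resno[1], 189L)
  expect_s3_class(ref$motif[[2]], "simple_graph")
  expect_error(reference_set(), "at least one")
  expect_error(
    reference_set(
      list(id = "a", residue = list(resname = "ASP", resno = 1)),
      list(id = "a", residue = list(resname = "GLU", resno = 2))
    ),
    "unique"
  )
})

test_that("reference sets round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "- id: rII",
    "  residue:",
    "    resname: ASP",
    "    resno: 189",
    "    side: P",
    "- id: rIV",
    "  motif:",
    "    nodes:",
    "      - {id: 1, label: DN}",
    "      - {id: 2, label: DN}",
    "      - {id: 3, label: AC}",
    "    edges:",
    "      - {from: 1, to: 3, label: hydrogen_bond}",
    "      - {from: 2, to: 3, label: hydrogen_bond}"
  ), path)
  ref <- read_reference_set(path)
  expect_equal(nrow(ref), 2)
  expect_equal(ref$side[1], "P")
  expect_equal(nrow(ref$motif[[2]]$edges), 2)
})

test_that("residue rules match through mapped atoms, motif rules through the pattern", {
  atoms <- tibble::tibble(
    atom_id = 1:2, side = c("P", "I"), label = c("AC/NG", "DN/PS"),
    x = c(0, 4.5), y = 0, z = 0,
    complex_id = "c1", chain = c("A", "B"),
    resname = c("ASP", "ARG"), resno = c(189L, 60L), insert = "",
    atom = c("OD1", "NH1")
  )
  g <- to_simple_graph(build_interface_graph(atoms, compute_contacts(atoms)))
  pat <- make_simple_graph(
    tibble::tibble(id = 1:2, label = c("NG", "PS")),
    tibble::tibble(from = 1, to = 2, label = "salt_bridge")
  )
  pats <- tibble::tibble(
    pattern_id = "p0", occurrences = list("g0"), graph = list(pat)
  )
  maps <- map_all(pats, list(g0 = g))
  ref <- reference_set(
    list(id = "hit", residue = list(resname = "ASP", resno = 189)),
    list(id = "wrong-resno", residue = list(resname = "ASP", resno = 1)),
    list(id = "bridge", motif = make_simple_graph(
      tibble::tibble(id = 1:2, label = c("NG", "PS")),
      tibble::tibble(from = 1, to = 2, label = "salt_bridge")
    )),
    list(id = "no-such-motif", motif = make_simple_graph(
      tibble::tibble(id = 1:2, label = c("AR", "AR")),
      tibble::tibble(from = 1, to = 2, label = "aromatic_stacking")
    ))
  )
  rel <- pattern_relevance(pats, maps, ref)
  expect_setequal(rel$matched[[1]], c("hit", "bridge"))
})

test_that("side-restricted residue rules respect the interface side", {
  atoms <- tibble::tibble(
    atom_id = 1:2, side = c("P", "I"), label = c("AC/NG", "DN/PS"),
    x = c(0, 4.5), y = 0, z = 0,
    complex_id = "c1", chain = c("A", "B"),
    resname = c("ASP", "ARG"), resno = c(189L, 60L), insert = "",
    atom = c("OD1", "NH1")
  )
  g <- to_simple_graph(build_interface_graph(atoms, compute_contacts(atoms)))
  pat <- make_simple_graph(
    tibble::tibble(id = 1:2, label = c("NG", "PS")),
    tibble::tibble(from = 1, to = 2, label = "salt_bridge")
  )
  pats <- tibble::tibble(
    pattern_id = "p0", occurrences = list("g0"), graph = list(pat)
  )
  maps <- map_all(pats, list(g0 = g))
  ref <- reference_set(
    list(id = "right-side", residue = list(resname = "ASP", resno = 189, side = "P")),
    list(id = "wrong-side", residue = list(resname = "ASP", resno = 189, side = "I"))
  )
  rel <- pattern_relevance(pats, maps, ref)
  expect_equal(rel$matched[[1]], "right-side")
})

test_that("precision and recall pool correctly across groups", {
  ref <- reference_set(
    list(id = "r1", residue = list(resname = "ASP", resno = 1)),
    list(id = "r2", residue = list(resname = "GLU", resno = 2))
  )
  relevance <- tibble::tibble(
    group = c("g1", "g1", "g1", "g2"),
    pattern_id = c("a", "b", "c", "d"),
    matched = list("r1", character(0), "r1", c("r1", "r2"))
  )
  rep <- precision_recall(relevance, ref)
  g1 <- rep[rep$group == "g1", ]
  expect_equal(g1$precision, round(2 / 3, 2))
  expect_equal(g1$recall, 0.5)
  g2 <- rep[rep$group == "g2", ]
  expect_equal(g2$precision, 1)
  expect_equal(g2$recall, 1)
  all_row <- rep[rep$group == "All", ]
  expect_equal(all_row$patterns, 4)
  expect_equal(all_row$precision, 0.75)
  expect_equal(all_row$recall, 1)
  expect_equal(all_row$residues, "r1,r2")
})
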