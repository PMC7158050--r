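path3 <- function(labels = c("A", "B", "C"), elabels = c("x", "y")) {
  make_simple_graph(
    nodes = tibble::tibble(id = 1:3, label = labels),
    edges = tibble::tibble(from = c(1, 2), to = c(2, 3), label = elabels)
  )
}

test_that("the minimum DFS code is invariant under node relabeling", {
  set.seed(31)
  for (trial in 1:20) {
    g <- random_labeled_graph(
      sample(3:6, 1), sample(0:2, 1),
      node_labels = c("A", "B"), edge_labels = c("x", "y")
    )
    code <- min_dfs_code(g)
    perm <- sample(nrow(g$nodes))
    remap <- stats::setNames(perm, g$nodes$id)
    gp <- make_simple_graph(
      nodes = tibble::tibble(
        id = unname(remap[as.character(g$nodes$id)]),
        label = g$nodes$label
      ),
      edges = tibble::tibble(
        from = unname(remap[as.character(g$edges$from)]),
        to = unname(remap[as.character(g$edges$to)]),
        label = g$edges$label
      )
    )
    expect_identical(min_dfs_code(gp), code)
  }
})

test_that("distinct labelings give distinct codes", {
  expect_false(
    min_dfs_code(path3(c("A", "B", "C"))) ==
      min_dfs_code(path3(c("C", "B", "A")))
  )
  expect_false(
    min_dfs_code(path3(elabels = c("x", "y"))) ==
      min_dfs_code(path3(elabels = c("x", "x")))
  )
})

test_that("mining two identical paths finds every connected subpattern", {
  gs <- list(path3(), path3())
  pats <- gspan(gs, 1.0)
  # subpatterns: A-x-B, B-y-C, A-x-B-y-C
  expect_equal(nrow(pats), 3)
  expect_equal(sort(pats$n_edges), c(1, 1, 2))
  expect_true(all(pats$support_count == 2))
  expect_true(all(pats$support_fraction == 1))
  mx <- filter_maximal(pats)
  expect_equal(nrow(mx), 1)
  expect_equal(mx$n_edges, 2)
})

test_that("support counts transactions, not embeddings", {
  # one graph containing the 1-edge pattern twice still counts once
  g <- make_simple_graph(
    nodes = tibble::tibble(id = 1:4, label = c("A", "B", "A", "B")),
    edges = tibble::tibble(from = c(1, 3, 2), to = c(2, 4, 3), label = "x")
  )
  pats <- gspan(list(g), 1.0)
  one_edge <- pats[pats$n_edges == 1 & pats$dfs_code == min_dfs_code(
    make_simple_graph(
      tibble::tibble(id = 1:2, label = c("A", "B")),
      tibble::tibble(from = 1, to = 2, label = "x")
    )
  ), ]
  expect_equal(one_edge$support_count, 1L)
})

test_that("pattern counts are anti-monotone in the support threshold", {
  set.seed(32)
  gs <- lapply(1:6, function(i) {
    random_labeled_graph(5, 1, c("A", "B"), c("x", "y"))
  })
  sweep <- support_sweep(gs, grid = seq(0.2, 1.0, by = 0.2))
  expect_true(all(diff(sweep$n_patterns) <= 0))
  expect_true(all(sweep$n_maximal <= sweep$n_patterns))
})

test_that("the node cap stops growth but keeps backward closures", {
  # triangle: with a 3-node cap the triangle itself must still be found
  tri <- make_simple_graph(
    nodes = tibble::tibble(id = 1:3, label = "A"),
    edges = tibble::tibble(from = c(1, 1, 2), to = c(2, 3, 3), label = "x")
  )
  pats <- gspan(list(tri, tri), 1.0, max_pattern_nodes = 3)
  expect_true(any(pats$n_edges == 3))
  expect_true(all(pats$n_nodes <= 3))
  # with a 2-node cap only single edges survive
  pats2 <- gspan(list(tri, tri), 1.0, max_pattern_nodes = 2)
  expect_true(all(pats2$n_nodes <= 2))
})

test_that("occurrence lists use the dataset's graph ids", {
  gs <- list(ga = path3(), gb = path3(c("A", "B", "Z")))
  pats <- gspan(gs, 0.5)
  ab <- pats[vapply(
    pats$occurrences, function(o) identical(sort(o), c("ga", "gb")),
    logical(1)
  ), ]
  expect_true(nrow(ab) >= 1) # the shared A-x-B edge occurs in both
  expect_true(all(unlist(pats$occurrences) %in% c("ga", "gb")))
})

test_that("patterns are reported in canonical order with canonical codes", {
  set.seed(33)
  gs <- lapply(1:4, function(i) {
    random_labeled_graph(5, 1, c("A", "B"), c("x", "y"))
  })
  pats <- gspan(gs, 0.5)
  expect_true(all(diff(pats$n_edges) >= 0))
  for (r in seq_len(nrow(pats))) {
    expect_identical(pats$dfs_code[r], min_dfs_code(pats$graph[[r]]))
  }
  expect_equal(anyDuplicated(pats$dfs_code), 0L)
})

test_that("mining validates its inputs", {
  expect_error(gspan(list(), 0.5), "empty")
  expect_error(gspan(list(path3()), 0), "min_support")
  expect_error(gspan(list(path3()), 1.2), "min_support")
})
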