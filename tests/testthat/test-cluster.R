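planted_blobs <- function(centers, per = 10, sd = 0.5) {
  m <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(
      rnorm(per, centers[i, 1], sd),
      rnorm(per, centers[i, 2], sd)
    )
  }))
  rownames(m) <- as.character(seq_len(nrow(m)) - 1L)
  m
}

test_that("the kNN graph is symmetric, hollow and respects k", {
  set.seed(21)
  m <- matrix(rnorm(40), ncol = 2)
  adj <- knn_graph(m, k = 3)
  expect_equal(adj, t(adj))
  expect_equal(diag(adj), rep(0, 20))
  # union symmetrization: each row has at least k neighbors
  expect_true(all(rowSums(adj > 0) >= 3))
  expect_error(knn_graph(m, k = 0), "k must")
  expect_error(knn_graph(m, k = 20), "k must")
})

test_that("gaussian weights decay with distance", {
  m <- rbind(c(0, 0), c(1, 0), c(5, 0))
  adj <- knn_graph(m, k = 2, weights = "gaussian", sigma = 1)
  expect_gt(adj[1, 2], adj[1, 3])
  expect_true(all(adj >= 0 & adj <= 1))
})

test_that("select_k returns the first connected neighbor count", {
  set.seed(22)
  # two tight, distant blobs: small k is disconnected, larger k bridges
  m <- planted_blobs(rbind(c(0, 0), c(100, 0)), per = 10, sd = 0.1)
  k <- select_k(m)
  expect_false(.adj_connected_oracle(knn_graph(m, max(1, k - 1))))
  expect_true(.adj_connected_oracle(knn_graph(m, k)))
})

test_that("eigen-gap recovers exact component counts and breaks ties low", {
  # block-diagonal adjacency with 3 exact components: eigenvalue 0 has
  # multiplicity 3, so the gap sits at n = 3
  adj <- matrix(0, 12, 12)
  for (b in 0:2) {
    idx <- b * 4 + 1:4
    adj[idx, idx] <- 1
  }
  diag(adj) <- 0
  ev <- eigen((diag(12) - diag(1 / sqrt(rowSums(adj))) %*% adj %*%
    diag(1 / sqrt(rowSums(adj)))), symmetric = TRUE)$values
  expect_equal(eigen_gap(sort(ev)), 3L)
  expect_error(eigen_gap(c(0, 1)), "at least 3")
  expect_error(eigen_gap(c(0, 1, 0.5, 2)), "ascending")
  # ties go to the smaller n
  expect_equal(eigen_gap(c(0, 0, 1, 1, 2)), 2L)
})

test_that("spectral clustering recovers well-separated planted groups", {
  set.seed(23)
  m <- planted_blobs(rbind(c(0, 0), c(20, 0), c(0, 20)), per = 8, sd = 0.5)
  k <- select_k(m)
  # with equal-size blobs the first connected k forces every point to have
  # one cross-blob neighbor; Gaussian weights shrink those bridges so the
  # planted partition is recovered exactly
  cl <- suppressWarnings(
    spectral_cluster(m, n = 3, k = k, weights = "gaussian", seed = 0)
  )
  truth <- rep(1:3, each = 8)
  tab <- table(truth, cl$assignments$cluster)
  expect_true(all(apply(tab, 1, max) == 8)) # each blob lands in one cluster
  expect_setequal(cl$assignments$cluster, 0:2)
  # cluster ids are 0-based and relabeled by first appearance
  expect_equal(cl$assignments$cluster[1], 0L)
  # the binary-weight partition is still a valid 3-way clustering with a
  # large majority of each blob kept together
  clb <- spectral_cluster(m, n = 3, k = k, seed = 0)
  tabb <- table(truth, clb$assignments$cluster)
  expect_setequal(clb$assignments$cluster, 0:2)
  expect_true(all(apply(tabb, 1, max) >= 6))
})

test_that("clustering is deterministic for a fixed seed", {
  set.seed(24)
  m <- planted_blobs(rbind(c(0, 0), c(15, 0)), per = 10, sd = 1)
  k <- select_k(m)
  a <- spectral_cluster(m, n = 2, k = k, seed = 7)
  b <- spectral_cluster(m, n = 2, k = k, seed = 7)
  expect_identical(a$assignments, b$assignments)
})

test_that("tidy and glance expose assignments and parameters", {
  set.seed(25)
  m <- planted_blobs(rbind(c(0, 0), c(15, 0)), per = 6, sd = 0.5)
  cl <- spectral_cluster(m, n = 2, k = select_k(m), seed = 0)
  td <- generics::tidy(cl)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("graph_id", "cluster"))
  gl <- generics::glance(cl)
  expect_equal(gl$n_graphs, 12)
  expect_equal(gl$n_clusters, 2)
})

test_that("joint parameter selection audits every qualifying rank", {
  set.seed(26)
  base <- planted_blobs(rbind(c(0, 0), c(30, 0)), per = 8, sd = 0.5)
  cm <- dplyr::bind_cols(
    tibble::tibble(graph_id = rownames(base)),
    tibble::as_tibble(as.data.frame(abs(round(base)) + 1),
      .name_repair = ~ c("a", "b")
    )
  )
  sel <- select_parameters(cm)
  expect_true(all(c("d", "variance", "k", "n") %in% names(sel$report)))
  expect_equal(sel$k, min(sel$report$k))
  expect_true(sel$d %in% sel$report$d)
  expect_true(sel$n %in% sel$report$n)
})
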