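#' k-nearest-neighbor similarity graph over graph feature rows
#'
#' Builds the undirected similarity graph that spectral clustering operates
#' on: one node per row of `theta`, with an edge between `i` and `j` when
#' `j` is among the `k` nearest rows of `i` by Euclidean distance or vice
#' versa (symmetrized union). Edge weights are binary by default; a
#' Gaussian similarity `exp(-dist^2 / (2 sigma^2))` is available.
#'
#' @param theta a `reduced_matrix` from [reduce_counting_matrix()], or a
#'   plain numeric matrix of row features.
#' @param k neighbor count, `1 <= k < nrow(theta)`.
#' @param weights `"binary"` (default) or `"gaussian"`.
#' @param sigma kernel bandwidth for Gaussian weights; default: median of
#'   the kNN distances.
#' @return A symmetric numeric adjacency matrix with zero diagonal.
#' @export
knn_graph <- function(theta, k, weights = c("binary", "gaussian"), sigma = NULL) {
  weights <- match.arg(weights)
  m <- if (inherits(theta, "reduced_matrix")) theta$theta else as.matrix(theta)
  r <- nrow(m)
  if (k < 1 || k >= r) stop("k must satisfy 1 <= k < number of rows (", r, ")")
  d <- as.matrix(stats::dist(m))
  adj <- matrix(0, r, r)
  for (i in seq_len(r)) {
    nn <- setdiff(order(d[i, ]), i)[seq_len(k)]
    adj[i, nn] <- 1
  }
  adj <- pmax(adj, t(adj)) # union symmetrization
  if (weights == "gaussian") {
    if (is.null(sigma)) {
      knd <- d[adj > 0]
      sigma <- stats::median(knd)
      if (!is.finite(sigma) || sigma <= 0) sigma <- 1
    }
    adj <- adj * exp(-d^2 / (2 * sigma^2))
  }
  diag(adj) <- 0
  rownames(adj) <- colnames(adj) <- rownames(m)
  adj
}

.adj_connected <- function(adj) {
  ig <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
  igraph::is_connected(ig)
}

#' Smallest neighbor count giving a connected similarity graph
#'
#' Sweeps `k = max(1, round(p * r))` over a percentage grid (1% to 90% of
#' the row count, step 1%, by default) and returns the first `k` whose
#' symmetrized kNN graph is fully connected. A disconnected similarity
#' graph would force its components to be clusters, which spectral
#' clustering should only do when the data genuinely demand it.
#'
#' @inheritParams knn_graph
#' @param p_grid increasing percentages in `(0, 0.9]`.
#' @return The selected integer `k`.
#' @export
select_k <- function(theta, p_grid = seq(0.01, 0.90, by = 0.01),
                     weights = "binary") {
  m <- if (inherits(theta, "reduced_matrix")) theta$theta else as.matrix(theta)
  r <- nrow(m)
  if (r < 3) stop("need at least 3 rows to select k")
  if (any(diff(p_grid) <= 0) || any(p_grid <= 0)) {
    stop("p_grid must be strictly increasing and positive")
  }
  ks <- unique(pmin(pmax(1L, as.integer(round(p_grid * r))), r - 1L))
  for (k in ks) {
    if (.adj_connected(knn_graph(m, k, weights = weights))) return(k)
  }
  stop(
    "no k in the percentage grid yields a connected similarity graph; ",
    "extend the grid beyond ", max(p_grid) * 100, "%"
  )
}

# internal: normalized symmetric Laplacian of an adjacency matrix
.laplacian <- function(adj) {
  deg <- rowSums(adj)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  diag(nrow(adj)) - (dinv * adj) %*% diag(dinv, nrow(adj))
}

# internal: ascending eigenvalues/vectors of the normalized Laplacian
.laplacian_spectrum <- function(adj) {
  e <- eigen((.laplacian(adj) + t(.laplacian(adj))) / 2, symmetric = TRUE)
  list(values = rev(e$values), vectors = e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE])
}

#' Eigen-gap heuristic for the number of clusters
#'
#' Chooses the cluster count `n` as the index (in `[2, n_max]`) at which
#' the difference between consecutive ascending eigenvalues of the
#' normalized graph Laplacian is maximal; ties go to the smaller `n`. On a
#' similarity graph with `m` exact connected components the zero eigenvalue
#' has multiplicity `m` and the heuristic recovers `n = m`.
#'
#' @param eigenvalues ascending Laplacian eigenvalues.
#' @param n_max largest candidate cluster count (default 30).
#' @return Integer cluster count `n >= 2`.
#' @export
eigen_gap <- function(eigenvalues, n_max = 30) {
  if (length(eigenvalues) < 3) stop("need at least 3 eigenvalues")
  if (any(diff(eigenvalues) < -1e-8)) stop("eigenvalues must be ascending")
  hi <- min(n_max, length(eigenvalues) - 1)
  if (hi < 2) stop("n_max too small")
  gaps <- eigenvalues[(2:hi) + 1] - eigenvalues[2:hi]
  as.integer((2:hi)[which.max(gaps)])
}

#' Spectral clustering of graph feature rows
#'
#' Clusters the rows of the reduced counting matrix: builds the kNN
#' similarity graph, embeds the rows into the eigenvectors of the `n`
#' smallest normalized-Laplacian eigenvalues (rows of the embedding
#' normalized to unit length), and partitions the embedded points with
#' seeded k-means.
#'
#' @inheritParams knn_graph
#' @param n number of clusters.
#' @param seed RNG seed for the k-means step (default 0).
#' @return An `interface_clustering` object with fields `assignments`
#'   (tibble `graph_id`, `cluster` in `[0, n)`), `k`, `n`, `d`,
#'   `eigenvalues` (ascending) and `seed`.
#' @export
spectral_cluster <- function(theta, n, k, weights = "binary", seed = 0) {
  m <- if (inherits(theta, "reduced_matrix")) theta$theta else as.matrix(theta)
  d_used <- if (inherits(theta, "reduced_matrix")) theta$d else ncol(m)
  r <- nrow(m)
  stopifnot(n >= 1, n <= r)
  adj <- knn_graph(m, k, weights = weights)
  if (!.adj_connected(adj)) {
    stop("similarity graph is disconnected at k = ", k, "; increase k")
  }
  sp <- .laplacian_spectrum(adj)
  emb <- sp$vectors[, seq_len(n), drop = FALSE]
  norms <- sqrt(rowSums(emb^2))
  emb <- emb / ifelse(norms > 0, norms, 1)
  cl <- local({
    set.seed(seed)
    if (n == r) {
      list(cluster = seq_len(r))
    } else {
      stats::kmeans(emb, centers = n, nstart = 20, iter.max = 100)
    }
  })
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(r) - 1L)
  # relabel clusters by first appearance for deterministic ids
  relabel <- match(cl$cluster, unique(cl$cluster)) - 1L
  out <- list(
    assignments = tibble::tibble(graph_id = ids, cluster = relabel),
    k = as.integer(k),
    n = as.integer(n),
    d = as.integer(d_used),
    eigenvalues = sp$values,
    seed = seed
  )
  class(out) <- "interface_clustering"
  out
}

#' @export
print.interface_clustering <- function(x, ...) {
  cat(
    "<interface_clustering> ", nrow(x$assignments), " graphs in ", x$n,
    " clusters (k = ", x$k, ", d = ", x$d, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname spectral_cluster
#' @param x an `interface_clustering` object.
#' @param ... unused.
#' @export
tidy.interface_clustering <- function(x, ...) {
  x$assignments
}

#' @rdname spectral_cluster
#' @export
glance.interface_clustering <- function(x, ...) {
  tibble::tibble(
    n_graphs = nrow(x$assignments),
    n_clusters = x$n,
    k = x$k,
    d = x$d,
    seed = x$seed
  )
}

#' Joint selection of rank, neighbor count and cluster count
#'
#' For every truncation rank `d` whose retained variance meets the
#' threshold, computes the minimal connected `k` ([select_k()]) and the
#' eigen-gap cluster count `n`, then selects: the minimal `k` over all
#' qualifying `d`; among ties on `k`, the `n` occurring most frequently
#' across qualifying ranks; and finally the smallest such `d`. The full
#' per-rank table is returned so the selection can be audited.
#'
#' @param cm counting-matrix tibble.
#' @param threshold variance threshold (default 0.95).
#' @param p_grid percentage grid for [select_k()].
#' @param n_max largest candidate cluster count.
#' @param weights edge weight scheme for the similarity graph.
#' @return A list with `d`, `n`, `k` and `report` (tibble of `d`,
#'   `variance`, `k`, `n` for every qualifying rank).
#' @export
select_parameters <- function(cm, threshold = 0.95,
                              p_grid = seq(0.01, 0.90, by = 0.01),
                              n_max = 30, weights = "binary") {
  x <- .cm_matrix(cm)
  s <- svd(x)
  pos <- sum(s$d > max(dim(x)) * .Machine$double.eps * s$d[1])
  sigma <- s$d[seq_len(pos)]
  dmin <- select_rank(sigma, threshold)
  rows <- purrr::map(dmin:pos, function(d) {
    red <- reduce_counting_matrix(cm, d = d)
    k <- select_k(red, p_grid = p_grid, weights = weights)
    adj <- knn_graph(red, k, weights = weights)
    n <- eigen_gap(.laplacian_spectrum(adj)$values, n_max = n_max)
    tibble::tibble(d = d, variance = red$variance_retained, k = k, n = n)
  })
  report <- dplyr::bind_rows(rows)
  kmin <- min(report$k)
  cand <- dplyr::filter(report, .data$k == kmin)
  tab <- table(cand$n)
  n_sel <- as.integer(names(tab)[which.max(tab)])
  d_sel <- min(cand$d[cand$n == n_sel])
  list(d = as.integer(d_sel), n = n_sel, k = as.integer(kmin), report = report)
}
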