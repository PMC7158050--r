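#' Canonical pair-label of two node label sets
#'
#' Each adjacent node pair of an interface graph is summarized by joining
#' the canonical serializations of its two endpoint label sets with `"-"`,
#' the two sides sorted lexicographically so the result is symmetric:
#' a donor node adjacent to an acceptor/negative node yields `"AC/NG-DN"`.
#'
#' @param a,b label sets: character vectors of labels or canonical label
#'   strings.
#' @return A single canonical pair-label string.
#' @export
#' @examples
#' pair_label("DN", c("ACP", "NEG"))    # "AC/NG-DN"
#' pair_label(c("DON", "POS"), "AC/NG") # "AC/NG-DN/PS"
pair_label <- function(a, b) {
  norm <- function(x) {
    if (length(x) == 1) {
      if (is.na(x) || x == "") return("")
      if (grepl("/", x, fixed = TRUE)) x <- split_label(x)
    }
    canonical_label(x)
  }
  ca <- norm(a)
  cb <- norm(b)
  if (ca == "" || cb == "") stop("pair_label requires non-empty label sets")
  sides <- sort(c(ca, cb))
  paste(sides, collapse = "-")
}

#' Build the counting matrix of a graph dataset
#'
#' Encodes every graph as a row of pair-label counts: each unordered node
#' pair joined by at least one edge contributes exactly one count to the
#' column named by [pair_label()] of its endpoints (edge multiplicity does
#' not matter; non-adjacent pairs contribute nothing). Columns are the
#' pair-labels occurring anywhere in the dataset, sorted lexicographically.
#'
#' @param dataset a graph dataset tibble from [build_graph_dataset()], or a
#'   list of `simple_graph`/`interface_graph` objects.
#' @param columns optional character vector of pair-label columns to use
#'   (unioned with the observed ones, then sorted); lets small worked
#'   examples be laid out over a fixed column universe.
#' @return A tibble with `graph_id` plus one integer column per pair-label.
#' @export
build_counting_matrix <- function(dataset, columns = NULL) {
  graphs <- .dataset_graphs(dataset)
  if (length(graphs) == 0) stop("counting matrix requires a non-empty dataset")
  ids <- names(graphs)
  per_graph <- purrr::map(graphs, function(g) {
    if (inherits(g, "interface_graph")) g <- to_simple_graph(g)
    if (nrow(g$edges) == 0) return(character(0))
    la <- g$nodes$label[match(g$edges$from, g$nodes$id)]
    lb <- g$nodes$label[match(g$edges$to, g$nodes$id)]
    mapply(pair_label, la, lb, USE.NAMES = FALSE)
  })
  cols <- sort(unique(c(unlist(per_graph), columns)))
  if (length(cols) == 0) stop("dataset has no edges; counting matrix is empty")
  counts <- t(vapply(
    per_graph,
    function(pl) as.integer(table(factor(pl, levels = cols))),
    integer(length(cols))
  ))
  out <- tibble::as_tibble(
    stats::setNames(as.data.frame(counts), cols),
    .name_repair = "minimal"
  )
  dplyr::bind_cols(tibble::tibble(graph_id = ids), out)
}

# internal: normalize the dataset argument to a named list of graphs
.dataset_graphs <- function(dataset) {
  if (is.data.frame(dataset)) {
    graphs <- dataset$graph
    names(graphs) <- as.character(dataset$graph_id)
  } else {
    graphs <- dataset
    if (is.null(names(graphs))) names(graphs) <- as.character(seq_along(graphs) - 1L)
  }
  graphs
}

# internal: numeric matrix of a counting-matrix tibble
.cm_matrix <- function(cm) {
  m <- as.matrix(cm[, setdiff(names(cm), "graph_id"), drop = FALSE])
  rownames(m) <- cm$graph_id
  storage.mode(m) <- "double"
  m
}

#' Smallest rank retaining a variance fraction
#'
#' Given the singular values of the (uncentered) counting matrix, returns
#' the smallest `d` such that the first `d` squared singular values hold at
#' least `threshold` of their total sum — i.e. the rank of the truncated SVD
#' that preserves the requested fraction of the data's variance.
#'
#' @param sigma numeric vector of singular values, sorted descending.
#' @param threshold variance fraction in `(0, 1]`; default `0.95`.
#' @return Integer rank `d`.
#' @export
select_rank <- function(sigma, threshold = 0.95) {
  if (length(sigma) == 0) stop("empty singular value vector")
  if (is.unsorted(rev(sigma))) stop("singular values must be sorted descending")
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  frac <- cumsum(sigma^2) / sum(sigma^2)
  as.integer(which(frac >= threshold - 1e-12)[1])
}

#' Truncated-SVD reduction of a counting matrix
#'
#' Factorizes the counting matrix `X = U Sigma V^T` and returns the reduced
#' representation `Theta = U_d Sigma_d` (an `r x d` matrix), which is the
#' best rank-`d` approximation of `X` in the least-squares sense projected
#' onto its first `d` right singular directions. `Theta` is the clustering
#' input: its rows preserve the pairwise geometry of the graphs' count
#' vectors up to the discarded variance.
#'
#' @param cm counting-matrix tibble from [build_counting_matrix()].
#' @param d retained rank; default `NULL` selects it with [select_rank()].
#' @param threshold variance threshold used when `d` is `NULL`.
#' @return A `reduced_matrix` object: list with `theta` (matrix, rownames =
#'   graph ids), `d`, `sigma` (all singular values), `variance_retained`.
#' @export
reduce_counting_matrix <- function(cm, d = NULL, threshold = 0.95) {
  x <- .cm_matrix(cm)
  s <- svd(x)
  pos <- sum(s$d > max(dim(x)) * .Machine$double.eps * s$d[1])
  sigma <- s$d[seq_len(pos)]
  if (is.null(d)) d <- select_rank(sigma, threshold)
  if (d < 1 || d > pos) stop("d must lie in [1, rank(X)] = [1, ", pos, "]")
  theta <- s$u[, seq_len(d), drop = FALSE] %*% diag(s$d[seq_len(d)], d, d)
  rownames(theta) <- rownames(x)
  out <- list(
    theta = theta,
    d = as.integer(d),
    sigma = sigma,
    variance_retained = sum(sigma[seq_len(d)]^2) / sum(sigma^2),
    v = s$v[, seq_len(d), drop = FALSE]
  )
  class(out) <- "reduced_matrix"
  out
}

#' @export
print.reduced_matrix <- function(x, ...) {
  cat(
    "<reduced_matrix> ", nrow(x$theta), " graphs x ", x$d,
    " components (", sprintf("%.1f", 100 * x$variance_retained),
    "% variance retained)\n",
    sep = ""
  )
  invisible(x)
}
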