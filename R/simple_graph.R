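#' Construct a labeled simple graph
#'
#' The mining stages operate on undirected simple graphs whose nodes and
#' edges carry string labels (canonical label-set serializations). This
#' constructor normalizes edge orientation (`from < to`), forbids self-loops
#' and parallel edges, and is used both by [to_simple_graph()] and by the
#' synthetic graph generators.
#'
#' @param nodes a tibble (or data frame) with columns `id` (integer) and
#'   `label` (character); extra provenance columns are preserved.
#' @param edges a tibble with columns `from`, `to` (node ids) and `label`.
#' @return A `simple_graph` object (list of `nodes` and `edges`).
#' @export
make_simple_graph <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "label") %in% names(nodes)))
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = integer(0), to = integer(0), label = character(0))
  }
  stopifnot(all(c("from", "to", "label") %in% names(edges)))
  nodes$id <- as.integer(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  if (!all(c(edges$from, edges$to) %in% nodes$id)) stop("edge endpoint not in nodes")
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  if (anyDuplicated(edges[, c("from", "to")])) stop("parallel edges are not allowed")
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  nodes <- dplyr::arrange(nodes, .data$id)
  g <- list(nodes = nodes, edges = edges)
  class(g) <- "simple_graph"
  g
}

#' @export
print.simple_graph <- function(x, ...) {
  cat(
    "<simple_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
    " edges; node labels: ",
    paste(utils::head(sort(unique(x$nodes$label)), 6), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Convert an interface multigraph to a labeled simple graph
#'
#' Collapses parallel edges between an atom pair into a single edge whose
#' label joins the sorted interaction types with `"/"` (e.g. a pair linked
#' by both a hydrogen bond and a salt bridge gets the edge label
#' `"hydrogen_bond/salt_bridge"`). Node labels are the pruned (retained)
#' label sets. Atom provenance travels along in the node table.
#'
#' @param g an `interface_graph`.
#' @return A `simple_graph` with one edge per adjacent atom pair.
#' @export
to_simple_graph <- function(g) {
  stopifnot(inherits(g, "interface_graph"))
  nodes <- tibble::tibble(
    id = g$nodes$atom_id,
    label = g$nodes$retained,
    complex_id = g$nodes$complex_id,
    chain = g$nodes$chain,
    resname = g$nodes$resname,
    resno = g$nodes$resno,
    insert = g$nodes$insert,
    atom = g$nodes$atom,
    side = g$nodes$side
  )
  edges <- g$edges |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(
      label = paste(sort(unique(.data$type)), collapse = "/"),
      .groups = "drop"
    )
  make_simple_graph(nodes, edges)
}

# internal: adjacency list (by position index) of a simple_graph
.adjacency <- function(g) {
  n <- nrow(g$nodes)
  pos <- match(c(g$edges$from, g$edges$to), g$nodes$id)
  adj <- vector("list", n)
  ef <- match(g$edges$from, g$nodes$id)
  et <- match(g$edges$to, g$nodes$id)
  for (k in seq_along(ef)) {
    adj[[ef[k]]] <- c(adj[[ef[k]]], et[k])
    adj[[et[k]]] <- c(adj[[et[k]]], ef[k])
  }
  adj
}

# internal: is the simple graph connected?
.sg_connected <- function(g) {
  n <- nrow(g$nodes)
  if (n <= 1) return(TRUE)
  adj <- .adjacency(g)
  seen <- logical(n)
  stack <- 1L
  seen[1] <- TRUE
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  all(seen)
}
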