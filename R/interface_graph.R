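#' Build a pruned bipartite interface multigraph
#'
#' Constructs the labeled bipartite multigraph G(P, I, E) of an interface:
#' nodes are exactly the atoms incident to at least one contact edge, and
#' each node's label set is pruned to the labels exercised by at least one
#' incident edge. An atom typed acceptor/negative whose only contact is a
#' salt bridge is therefore retained as negative only — the acceptor role
#' never materialized in an interaction.
#'
#' @param atoms labeled atom tibble ([assign_atom_labels()]).
#' @param edges contact edge tibble ([compute_contacts()]).
#' @return An `interface_graph`: a list with `nodes` (atom provenance,
#'   assigned `label`, pruned `retained` label string) and `edges`.
#' @export
build_interface_graph <- function(atoms, edges) {
  used <- sort(unique(c(edges$from, edges$to)))
  nodes <- dplyr::filter(atoms, .data$atom_id %in% used)
  lab <- stats::setNames(nodes$label, as.character(nodes$atom_id))
  retained <- stats::setNames(
    vector("list", nrow(nodes)), as.character(nodes$atom_id)
  )
  for (k in seq_len(nrow(edges))) {
    a <- as.character(edges$from[k])
    b <- as.character(edges$to[k])
    ty <- edges$type[k]
    la <- split_label(lab[[a]])
    lb <- split_label(lab[[b]])
    retained[[a]] <- union(retained[[a]], exercised_labels(la, lb, ty))
    retained[[b]] <- union(retained[[b]], exercised_labels(lb, la, ty))
  }
  nodes$retained <- unname(vapply(
    as.character(nodes$atom_id),
    function(id) canonical_label(retained[[id]] %||% character(0)),
    character(1)
  ))
  g <- list(nodes = nodes, edges = edges)
  class(g) <- "interface_graph"
  g
}

#' @export
print.interface_graph <- function(x, ...) {
  cat(
    "<interface_graph> ", nrow(x$nodes), " atoms (",
    sum(x$nodes$side == "P"), " P / ", sum(x$nodes$side == "I"), " I), ",
    nrow(x$edges), " interaction edges\n",
    sep = ""
  )
  invisible(x)
}

#' Connected components of an interface multigraph
#'
#' Splits an interface graph into its connected components; each component
#' is one graph of the mining dataset. Components are ordered by their
#' smallest contained atom id, so the decomposition is deterministic.
#'
#' @param g an `interface_graph`.
#' @return A list of connected `interface_graph` objects.
#' @export
extract_components <- function(g) {
  stopifnot(inherits(g, "interface_graph"))
  if (nrow(g$nodes) == 0) return(list())
  ids <- g$nodes$atom_id
  ig <- igraph::graph_from_data_frame(
    d = data.frame(
      from = as.character(g$edges$from),
      to = as.character(g$edges$to)
    ),
    directed = FALSE,
    vertices = data.frame(name = as.character(ids))
  )
  comp <- igraph::components(ig)
  membership <- comp$membership[as.character(ids)]
  groups <- split(ids, membership)
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  lapply(groups, function(atom_ids) {
    sub <- list(
      nodes = dplyr::filter(g$nodes, .data$atom_id %in% atom_ids),
      edges = dplyr::filter(
        g$edges, .data$from %in% atom_ids, .data$to %in% atom_ids
      )
    )
    class(sub) <- "interface_graph"
    sub
  })
}

#' Build the graph dataset for a set of complexes
#'
#' Runs the whole interface-graph stage for one or more complexes: assign
#' labels, compute contacts, build the pruned bipartite multigraph and
#' extract its connected components. Each connected component becomes one
#' dataset graph.
#'
#' @param atom_tables a list of atom tibbles (one per complex, from
#'   [read_interface_atoms()]), or a single tibble.
#' @param criteria contact criteria ([contact_criteria()]).
#' @param typing_table atom typing table ([default_typing_table()]).
#' @return A tibble with one row per dataset graph: `graph_id` (0-based, in
#'   dataset order), `complex_id`, `component`, `n_nodes`, `n_edges` and a
#'   `graph` list-column of `interface_graph` objects.
#' @export
build_graph_dataset <- function(atom_tables,
                                criteria = contact_criteria(),
                                typing_table = default_typing_table()) {
  if (is.data.frame(atom_tables)) atom_tables <- list(atom_tables)
  rows <- purrr::map(atom_tables, function(atoms) {
    if (!"label" %in% names(atoms)) {
      atoms <- assign_atom_labels(atoms, typing_table)
    }
    edges <- compute_contacts(atoms, criteria)
    comps <- extract_components(build_interface_graph(atoms, edges))
    if (length(comps) == 0) return(NULL)
    comps <- unname(comps)
    tibble::tibble(
      complex_id = comps[[1]]$nodes$complex_id[1],
      component = seq_along(comps) - 1L,
      n_nodes = vapply(comps, function(g) nrow(g$nodes), integer(1)),
      n_edges = vapply(comps, function(g) nrow(g$edges), integer(1)),
      graph = comps
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("no interface contacts found in any complex")
  out$graph_id <- seq_len(nrow(out)) - 1L
  dplyr::relocate(out, "graph_id")
}
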