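#' Convert a package graph to an igraph object
#'
#' @param g an `interface_graph` or `simple_graph`.
#' @return An undirected [igraph::igraph] with node/edge attributes
#'   (provenance, labels, interaction type, distance as applicable).
#' @export
as_igraph <- function(g) {
  if (inherits(g, "interface_graph")) {
    v <- data.frame(
      name = as.character(g$nodes$atom_id),
      chain = g$nodes$chain,
      resname = g$nodes$resname,
      resno = g$nodes$resno,
      atom = g$nodes$atom,
      side = g$nodes$side,
      label = g$nodes$label,
      retained = g$nodes$retained,
      stringsAsFactors = FALSE
    )
    e <- data.frame(
      from = as.character(g$edges$from),
      to = as.character(g$edges$to),
      type = g$edges$type,
      distance = g$edges$distance,
      stringsAsFactors = FALSE
    )
  } else if (inherits(g, "simple_graph")) {
    v <- as.data.frame(g$nodes)
    v <- cbind(name = as.character(v$id), v[, setdiff(names(v), "id"), drop = FALSE])
    e <- data.frame(
      from = as.character(g$edges$from),
      to = as.character(g$edges$to),
      label = g$edges$label,
      stringsAsFactors = FALSE
    )
  } else {
    stop("unsupported graph class")
  }
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
}

#' Write a graph dataset to disk
#'
#' Serializes the dataset as one JSON node-link file and one GraphML file
#' per complex (all of the complex's connected components together, each
#' node/edge tagged with its component index), plus a `manifest.json`
#' listing every dataset graph with its provenance.
#'
#' @param dataset a graph dataset tibble from [build_graph_dataset()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest tibble.
#' @export
write_graph_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cid in unique(dataset$complex_id)) {
    rows <- dataset[dataset$complex_id == cid, , drop = FALSE]
    nodes <- purrr::map2_dfr(rows$graph, rows$component, function(g, comp) {
      dplyr::mutate(g$nodes, component = comp)
    })
    edges <- purrr::map2_dfr(rows$graph, rows$component, function(g, comp) {
      dplyr::mutate(g$edges, component = comp)
    })
    payload <- list(
      complex_id = cid,
      nodes = nodes,
      edges = edges
    )
    jsonlite::write_json(
      payload, file.path(dir, paste0(cid, ".json")),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    merged <- list(nodes = nodes, edges = dplyr::rename(edges, label = "type"))
    ig <- igraph::graph_from_data_frame(
      d = data.frame(
        from = as.character(merged$edges$from),
        to = as.character(merged$edges$to),
        label = merged$edges$label,
        distance = merged$edges$distance,
        component = merged$edges$component
      ),
      directed = FALSE,
      vertices = data.frame(
        name = as.character(nodes$atom_id),
        chain = nodes$chain, resname = nodes$resname, resno = nodes$resno,
        atom = nodes$atom, side = nodes$side, label = nodes$label,
        retained = nodes$retained, component = nodes$component
      )
    )
    igraph::write_graph(ig, file.path(dir, paste0(cid, ".graphml")), format = "graphml")
  }
  manifest <- dataset[, c("graph_id", "complex_id", "component", "n_nodes", "n_edges")]
  jsonlite::write_json(
    manifest, file.path(dir, "manifest.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

#' Read a graph dataset written by [write_graph_dataset()]
#'
#' @param dir directory containing the per-complex JSON files and
#'   `manifest.json`.
#' @return A graph dataset tibble equivalent to the one written.
#' @export
read_graph_dataset <- function(dir) {
  manifest <- tibble::as_tibble(
    jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  )
  complexes <- unique(manifest$complex_id)
  graphs <- list()
  for (cid in complexes) {
    payload <- jsonlite::read_json(
      file.path(dir, paste0(cid, ".json")),
      simplifyVector = TRUE
    )
    nodes <- tibble::as_tibble(payload$nodes)
    edges <- tibble::as_tibble(payload$edges)
    for (comp in sort(unique(nodes$component))) {
      g <- list(
        nodes = dplyr::select(
          dplyr::filter(nodes, .data$component == comp), -"component"
        ),
        edges = dplyr::select(
          dplyr::filter(edges, .data$component == comp), -"component"
        )
      )
      class(g) <- "interface_graph"
      graphs[[paste(cid, comp)]] <- g
    }
  }
  manifest$graph <- purrr::map2(
    manifest$complex_id, manifest$component,
    function(cid, comp) graphs[[paste(cid, comp)]]
  )
  manifest$graph_id <- as.integer(manifest$graph_id)
  manifest
}

#' Write a pattern tibble to JSON
#'
#' Serializes mined patterns (DFS code, node labels — mined and display —
#' edge labels, supports, occurrence ids) to a JSON file.
#'
#' @param patterns a pattern tibble from [gspan()]/[filter_maximal()].
#' @param path output file.
#' @export
write_patterns <- function(patterns, path) {
  items <- purrr::map(seq_len(nrow(patterns)), function(r) {
    g <- patterns$graph[[r]]
    list(
      pattern_id = patterns$pattern_id[r],
      dfs_code = patterns$dfs_code[r],
      support_count = patterns$support_count[r],
      support_fraction = patterns$support_fraction[r],
      occurrences = as.list(patterns$occurrences[[r]]),
      is_maximal = if ("is_maximal" %in% names(patterns)) patterns$is_maximal[r] else NA,
      nodes = purrr::map(seq_len(nrow(g$nodes)), function(v) {
        list(
          id = g$nodes$id[v],
          label = g$nodes$label[v],
          display = suppressWarnings(derive_display_labels(g))[v]
        )
      }),
      edges = purrr::map(seq_len(nrow(g$edges)), function(k) {
        list(
          from = g$edges$from[k], to = g$edges$to[k],
          label = g$edges$label[k]
        )
      })
    )
  })
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pattern file written by [write_patterns()]
#'
#' @param path JSON file path.
#' @return A pattern tibble with rebuilt `simple_graph` objects.
#' @export
read_patterns <- function(path) {
  items <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(items) == 0) {
    return(tibble::tibble(
      pattern_id = integer(0), dfs_code = character(0), n_nodes = integer(0),
      n_edges = integer(0), support_count = integer(0),
      support_fraction = numeric(0), occurrences = list(), graph = list(),
      is_maximal = logical(0)
    ))
  }
  rows <- purrr::map(items, function(it) {
    nodes <- dplyr::bind_rows(purrr::map(it$nodes, function(v) {
      tibble::tibble(id = as.integer(v$id), label = v$label)
    }))
    edges <- if (length(it$edges) > 0) {
      dplyr::bind_rows(purrr::map(it$edges, function(e) {
        tibble::tibble(
          from = as.integer(e$from), to = as.integer(e$to), label = e$label
        )
      }))
    } else {
      tibble::tibble(from = integer(0), to = integer(0), label = character(0))
    }
    tibble::tibble(
      pattern_id = it$pattern_id,
      dfs_code = it$dfs_code,
      n_nodes = nrow(nodes),
      n_edges = nrow(edges),
      support_count = it$support_count,
      support_fraction = it$support_fraction,
      occurrences = list(as.character(unlist(it$occurrences))),
      graph = list(make_simple_graph(nodes, edges)),
      is_maximal = if (is.null(it$is_maximal)) NA else it$is_maximal
    )
  })
  dplyr::bind_rows(rows)
}

#' Write and read pattern-to-atom mapping tables
#'
#' Mappings are serialized as a JSON array with one object per mapping,
#' carrying the pattern id, target graph id, the per-node atom assignments
#' (with provenance) and the per-edge interaction assignments.
#'
#' @param mappings a mapping table from [map_all()] (optionally with a
#'   `cluster` column).
#' @param path JSON file path.
#' @return `write_mappings()` invisibly returns `path`; `read_mappings()`
#'   returns the mapping tibble.
#' @export
write_mappings <- function(mappings, path) {
  items <- purrr::map(seq_len(nrow(mappings)), function(r) {
    list(
      pattern_id = mappings$pattern_id[r],
      graph_id = mappings$graph_id[r],
      mapping_id = mappings$mapping_id[r],
      cluster = if ("cluster" %in% names(mappings)) mappings$cluster[r] else NULL,
      nodes = mappings$node_map[[r]],
      edges = mappings$edge_map[[r]]
    )
  })
  jsonlite::write_json(
    items, path,
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_mappings
#' @export
read_mappings <- function(path) {
  items <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(items) == 0 || (is.data.frame(items) && nrow(items) == 0)) {
    return(tibble::tibble(
      pattern_id = character(0), graph_id = character(0),
      mapping_id = integer(0), cluster = integer(0),
      node_map = list(), edge_map = list()
    ))
  }
  out <- tibble::tibble(
    pattern_id = items$pattern_id,
    graph_id = as.character(items$graph_id),
    mapping_id = items$mapping_id,
    node_map = purrr::map(items$nodes, tibble::as_tibble),
    edge_map = purrr::map(items$edges, tibble::as_tibble)
  )
  if (!is.null(items$cluster)) out$cluster <- items$cluster
  out
}
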