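#' Line graph of a labeled simple graph
#'
#' Builds L(H): one node per edge of `H`, carrying the source edge's label
#' and the labels of its two endpoints; two line-graph nodes are adjacent
#' iff their source edges share an endpoint. Mined patterns are not
#' necessarily vertex-induced subgraphs of their occurrence graphs, but
#' their line graphs are matched as ordinary subgraphs, which is why the
#' mapping stage works on L(pattern) and L(graph). Because K3 and K1,3
#' share a line graph without being isomorphic, every line-graph match is
#' re-verified on the original graphs before it is reported.
#'
#' @param h a `simple_graph` with at least one edge.
#' @return A `line_graph`: list with `nodes` (tibble `id`, `label`,
#'   `end_a`, `end_b`, `src_from`, `src_to`) and `edges` (tibble `from`,
#'   `to` of line-node ids).
#' @export
line_graph <- function(h) {
  stopifnot(inherits(h, "simple_graph"))
  ne <- nrow(h$edges)
  if (ne == 0) stop("line graph of an edgeless graph is undefined here")
  lab_of <- stats::setNames(h$nodes$label, as.character(h$nodes$id))
  nodes <- tibble::tibble(
    id = seq_len(ne),
    label = h$edges$label,
    end_a = unname(lab_of[as.character(h$edges$from)]),
    end_b = unname(lab_of[as.character(h$edges$to)]),
    src_from = h$edges$from,
    src_to = h$edges$to
  )
  from <- integer(0)
  to <- integer(0)
  if (ne > 1) {
    for (a in 1:(ne - 1)) {
      for (b in (a + 1):ne) {
        share <- length(intersect(
          c(nodes$src_from[a], nodes$src_to[a]),
          c(nodes$src_from[b], nodes$src_to[b])
        )) > 0
        if (share) {
          from <- c(from, a)
          to <- c(to, b)
        }
      }
    }
  }
  lg <- list(nodes = nodes, edges = tibble::tibble(from = from, to = to))
  class(lg) <- "line_graph"
  lg
}

# are two line-graph nodes compatible under subset-label matching?
# (edge labels compatible, and endpoint label pairs compatible in some
# orientation)
.line_nodes_compatible <- function(pn, tn) {
  if (!labels_compatible(pn$label, tn$label)) return(FALSE)
  (labels_compatible(pn$end_a, tn$end_a) && labels_compatible(pn$end_b, tn$end_b)) ||
    (labels_compatible(pn$end_a, tn$end_b) && labels_compatible(pn$end_b, tn$end_a))
}

# enumerate monomorphisms of pattern line graph into target line graph
# (VF2-style backtracking); returns list of integer vectors (pattern line
# node -> target line node)
.line_embeddings <- function(lp, lt) {
  np <- nrow(lp$nodes)
  nt <- nrow(lt$nodes)
  if (np > nt) return(list())
  padj <- .lg_adj(lp)
  tadj <- .lg_adj(lt)
  # order pattern line nodes so each new one touches a mapped one if possible
  ord <- 1L
  seen <- logical(np)
  seen[1] <- TRUE
  while (length(ord) < np) {
    nxt <- NA_integer_
    for (v in seq_len(np)) {
      if (!seen[v] && any(padj[[v]] %in% ord)) {
        nxt <- v
        break
      }
    }
    if (is.na(nxt)) nxt <- which(!seen)[1]
    seen[nxt] <- TRUE
    ord <- c(ord, nxt)
  }
  st <- new.env(parent = emptyenv())
  st$found <- list()
  map <- rep(NA_integer_, np)
  used <- logical(nt)
  bt <- function(pos) {
    if (pos > np) {
      st$found[[length(st$found) + 1]] <- map
      return()
    }
    v <- ord[pos]
    for (cand in seq_len(nt)) {
      if (used[cand]) next
      if (!.line_nodes_compatible(lp$nodes[v, ], lt$nodes[cand, ])) next
      ok <- TRUE
      for (w in padj[[v]]) {
        if (!is.na(map[w]) && !(map[w] %in% tadj[[cand]])) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      map[v] <<- cand
      used[cand] <<- TRUE
      bt(pos + 1)
      map[v] <<- NA_integer_
      used[cand] <<- FALSE
    }
  }
  bt(1)
  st$found
}

.lg_adj <- function(lg) {
  n <- nrow(lg$nodes)
  adj <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(lg$edges))) {
    a <- lg$edges$from[k]
    b <- lg$edges$to[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Map a mined pattern onto a target graph
#'
#' Finds every embedding of a frequent pattern into a labeled simple graph
#' through line-graph matching: the pattern's line graph is matched into the
#' target's line graph (subset-label compatibility on edge labels and
#' endpoint labels, display labels on the pattern side), each line-graph
#' match is back-translated into an edge map, the induced node map is
#' reconstructed, and the result is verified edge by edge on the original
#' graphs — injectivity, adjacency and label compatibility — which discards
#' the K3/K1,3-type artifacts of line-graph isomorphism. Mappings are
#' deduplicated by their node-map image.
#'
#' @param pattern a `simple_graph` pattern, or one row of a [gspan()]
#'   pattern tibble.
#' @param g the target `simple_graph`.
#' @return A tibble with one row per distinct mapping: `mapping_id`,
#'   `node_map` (list of tibbles `pattern_node`, `target_id`, plus any
#'   provenance columns of `g`), `edge_map` (list of tibbles
#'   `pattern_edge`, `target_from`, `target_to`, `target_label`).
#' @export
map_pattern <- function(pattern, g) {
  pg <- if (inherits(pattern, "simple_graph")) pattern else pattern$graph[[1]]
  stopifnot(inherits(pg, "simple_graph"), inherits(g, "simple_graph"))
  if (nrow(pg$edges) == 0) stop("cannot map a pattern without edges")
  # pattern side matches with display labels
  disp <- suppressWarnings(derive_display_labels(pg))
  pgd <- pg
  pgd$nodes$label <- disp
  lp <- line_graph(pgd)
  lt <- line_graph(g)
  lembs <- .line_embeddings(lp, lt)

  npn <- nrow(pg$nodes)
  tlab <- g$nodes$label
  # target adjacency edge label lookup by position pair
  tkey <- paste(
    pmin(match(g$edges$from, g$nodes$id), match(g$edges$to, g$nodes$id)),
    pmax(match(g$edges$from, g$nodes$id), match(g$edges$to, g$nodes$id))
  )
  telab <- stats::setNames(g$edges$label, tkey)
  pef <- match(pg$edges$from, pg$nodes$id)
  pet <- match(pg$edges$to, pg$nodes$id)

  seen_maps <- character(0)
  rows <- list()
  for (le in lembs) {
    # le: pattern edge k -> target edge le[k]; recover node maps by choosing
    # an orientation per edge consistently
    tf <- match(g$edges$from, g$nodes$id)[le]
    tt <- match(g$edges$to, g$nodes$id)[le]
    vmaps <- list(rep(NA_integer_, npn))
    for (k in seq_along(pef)) {
      nxt <- list()
      for (vm in vmaps) {
        for (orient in 1:2) {
          x <- if (orient == 1) tf[k] else tt[k]
          y <- if (orient == 1) tt[k] else tf[k]
          u <- pef[k]; v <- pet[k]
          if (!is.na(vm[u]) && vm[u] != x) next
          if (!is.na(vm[v]) && vm[v] != y) next
          vm2 <- vm
          vm2[u] <- x
          vm2[v] <- y
          nxt[[length(nxt) + 1]] <- vm2
        }
      }
      vmaps <- nxt
      if (length(vmaps) == 0) break
    }
    for (vm in vmaps) {
      # verification on the original graphs
      if (anyDuplicated(vm[!is.na(vm)]) > 0) next
      if (any(is.na(vm))) next
      ok <- TRUE
      for (v in seq_len(npn)) {
        if (!labels_compatible(disp[v], tlab[vm[v]])) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        for (k in seq_along(pef)) {
          key <- paste(min(vm[pef[k]], vm[pet[k]]), max(vm[pef[k]], vm[pet[k]]))
          bl <- telab[key]
          if (is.na(bl) || !labels_compatible(pg$edges$label[k], bl)) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) next
      sig <- paste(vm, collapse = ",")
      if (sig %in% seen_maps) next
      seen_maps <- c(seen_maps, sig)
      node_map <- dplyr::bind_cols(
        tibble::tibble(pattern_node = pg$nodes$id),
        stats::setNames(
          g$nodes[vm, , drop = FALSE],
          paste0("target_", names(g$nodes))
        )
      )
      edge_map <- tibble::tibble(
        pattern_edge = seq_along(pef),
        target_from = g$nodes$id[vm[pef]],
        target_to = g$nodes$id[vm[pet]],
        target_label = unname(telab[paste(
          pmin(vm[pef], vm[pet]), pmax(vm[pef], vm[pet])
        )])
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        node_map = list(node_map),
        edge_map = list(edge_map)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      mapping_id = integer(0), node_map = list(), edge_map = list()
    ))
  }
  out <- dplyr::bind_rows(rows)
  out$mapping_id <- seq_len(nrow(out)) - 1L
  dplyr::relocate(out, "mapping_id")
}

#' Map every pattern onto each of its occurrence graphs
#'
#' Runs [map_pattern()] for each (pattern, occurrence graph) pair and
#' asserts that every occurrence claimed by the miner yields at least one
#' verified mapping; a zero-mapping occurrence indicates a miner/mapper
#' disagreement and raises an error.
#'
#' @param patterns a pattern tibble from [gspan()] or [filter_maximal()].
#' @param dataset a graph dataset tibble ([build_graph_dataset()]) or a
#'   named list of `simple_graph`s keyed by graph id.
#' @return A tibble with one row per mapping: `pattern_id`, `graph_id`,
#'   `mapping_id`, `node_map`, `edge_map`.
#' @export
map_all <- function(patterns, dataset) {
  graphs <- .dataset_graphs(dataset)
  graphs <- lapply(graphs, function(g) {
    if (inherits(g, "interface_graph")) to_simple_graph(g) else g
  })
  rows <- list()
  for (r in seq_len(nrow(patterns))) {
    occ <- patterns$occurrences[[r]]
    for (gid in occ) {
      g <- graphs[[as.character(gid)]]
      if (is.null(g)) stop("occurrence graph ", gid, " not present in dataset")
      m <- map_pattern(patterns$graph[[r]], g)
      if (nrow(m) == 0) {
        stop(
          "pattern ", patterns$pattern_id[r], " claims occurrence in graph ",
          gid, " but no verified mapping exists"
        )
      }
      m$pattern_id <- patterns$pattern_id[r]
      m$graph_id <- as.character(gid)
      rows[[length(rows) + 1]] <- m
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      pattern_id = integer(0), graph_id = character(0), mapping_id = integer(0),
      node_map = list(), edge_map = list()
    ))
  }
  dplyr::relocate(
    dplyr::bind_rows(rows), "pattern_id", "graph_id", "mapping_id"
  )
}

#' Residues touched by each pattern
#'
#' Summarizes a mapping table at residue level: for every pattern, the
#' union over its mappings of the residues its mapped atoms belong to.
#'
#' @param mappings a mapping table from [map_all()].
#' @return A tibble: `pattern_id`, `complex_id`, `chain`, `resname`,
#'   `resno`, deduplicated.
#' @export
pattern_residues <- function(mappings) {
  if (nrow(mappings) == 0) {
    return(tibble::tibble(
      pattern_id = integer(0), complex_id = character(0), chain = character(0),
      resname = character(0), resno = integer(0)
    ))
  }
  mappings |>
    dplyr::mutate(
      res = purrr::map(.data$node_map, function(nm) {
        cols <- intersect(
          c("target_complex_id", "target_chain", "target_resname", "target_resno"),
          names(nm)
        )
        dplyr::distinct(nm[, cols, drop = FALSE])
      })
    ) |>
    dplyr::select("pattern_id", "res") |>
    tidyr::unnest("res") |>
    dplyr::rename_with(~ sub("^target_", "", .x)) |>
    dplyr::distinct()
}
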