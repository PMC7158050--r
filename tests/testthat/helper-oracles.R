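# Independent brute-force oracles used to validate the mining, mapping and
# rank-selection implementations. These deliberately share no search code
# with the package: frequent-subgraph counting enumerates connected edge
# subsets and groups them with igraph's VF2 isomorphism test; pattern
# mapping enumerates all injective node maps directly; rank selection uses
# an eigendecomposition of X'X instead of the SVD.

# ---- random labeled graphs ----------------------------------------------

# connected random simple graph: random spanning tree plus extra edges
random_labeled_graph <- function(n_nodes, extra_edges, node_labels, edge_labels) {
  nodes <- tibble::tibble(
    id = seq_len(n_nodes),
    label = sample(node_labels, n_nodes, replace = TRUE)
  )
  from <- integer(0)
  to <- integer(0)
  if (n_nodes > 1) {
    for (v in 2:n_nodes) {
      from <- c(from, sample.int(v - 1, 1))
      to <- c(to, v)
    }
  }
  guard <- 0L
  while (extra_edges > 0 && guard < 100) {
    guard <- guard + 1L
    uv <- sort(sample.int(n_nodes, 2))
    key <- paste(uv[1], uv[2])
    if (key %in% paste(pmin(from, to), pmax(from, to))) next
    from <- c(from, uv[1])
    to <- c(to, uv[2])
    extra_edges <- extra_edges - 1L
  }
  edges <- tibble::tibble(
    from = from, to = to,
    label = sample(edge_labels, length(from), replace = TRUE)
  )
  make_simple_graph(nodes, edges)
}

# ---- FSM oracle ----------------------------------------------------------

oracle_colored_igraph <- function(g, node_labels, edge_labels) {
  ig <- as_igraph(g)
  igraph::V(ig)$color <- match(igraph::V(ig)$label, node_labels)
  igraph::E(ig)$color <- match(igraph::E(ig)$label, edge_labels)
  ig
}

oracle_iso <- function(a, b) {
  igraph::vcount(a) == igraph::vcount(b) &&
    igraph::ecount(a) == igraph::ecount(b) &&
    igraph::isomorphic(
      a, b,
      method = "vf2",
      vertex.color1 = igraph::V(a)$color, vertex.color2 = igraph::V(b)$color,
      edge.color1 = igraph::E(a)$color, edge.color2 = igraph::E(b)$color
    )
}

# all connected subgraphs (>= 1 edge) of g as simple_graph objects
oracle_connected_subgraphs <- function(g) {
  ne <- nrow(g$edges)
  out <- list()
  if (ne == 0) return(out)
  pos_from <- match(g$edges$from, g$nodes$id)
  pos_to <- match(g$edges$to, g$nodes$id)
  for (sz in seq_len(ne)) {
    for (comb in utils::combn(ne, sz, simplify = FALSE)) {
      # connectivity over the chosen edges
      verts <- unique(c(pos_from[comb], pos_to[comb]))
      reach <- verts[1]
      repeat {
        grown <- FALSE
        for (k in comb) {
          a <- pos_from[k]
          b <- pos_to[k]
          if (a %in% reach && !(b %in% reach)) {
            reach <- c(reach, b)
            grown <- TRUE
          } else if (b %in% reach && !(a %in% reach)) {
            reach <- c(reach, a)
            grown <- TRUE
          }
        }
        if (!grown) break
      }
      if (length(reach) < length(verts)) next
      ids <- g$nodes$id[verts]
      out[[length(out) + 1]] <- make_simple_graph(
        g$nodes[g$nodes$id %in% ids, , drop = FALSE],
        g$edges[comb, , drop = FALSE]
      )
    }
  }
  out
}

# transaction supports of all isomorphism classes of connected subgraphs;
# returns a list of (graph = representative, support = count)
oracle_frequent_subgraphs <- function(graphs, min_support,
                                      node_labels, edge_labels) {
  classes <- list() # colored igraphs
  reps <- list() # simple_graph representatives
  counts <- integer(0)
  for (g in graphs) {
    subs <- oracle_connected_subgraphs(g)
    igs <- lapply(subs, oracle_colored_igraph, node_labels, edge_labels)
    hit <- logical(length(classes))
    for (si in seq_along(subs)) {
      found <- 0L
      for (ci in seq_along(classes)) {
        if (oracle_iso(classes[[ci]], igs[[si]])) {
          found <- ci
          break
        }
      }
      if (found == 0L) {
        classes[[length(classes) + 1]] <- igs[[si]]
        reps[[length(reps) + 1]] <- subs[[si]]
        counts <- c(counts, 0L)
        hit <- c(hit, FALSE)
        found <- length(classes)
      }
      if (!hit[found]) {
        counts[found] <- counts[found] + 1L
        hit[found] <- TRUE
      }
    }
  }
  minsup <- ceiling(min_support * length(graphs) - 1e-9)
  keep <- which(counts >= minsup)
  list(graphs = reps[keep], supports = counts[keep])
}

# ---- mapping oracle ------------------------------------------------------

# subset-label compatibility, written independently of the package helper
oracle_compatible <- function(a, b) {
  sa <- strsplit(a, "/", fixed = TRUE)[[1]]
  sb <- strsplit(b, "/", fixed = TRUE)[[1]]
  all(sa %in% sb) || all(sb %in% sa)
}

# every injective node map of `pattern` (display labels already applied)
# into `target` under subset-label compatibility on nodes and edges;
# returns a character vector of signatures "t1,t2,..." (target node ids in
# pattern node order) for set comparison
oracle_embeddings <- function(pattern, target) {
  np <- nrow(pattern$nodes)
  nt <- nrow(target$nodes)
  if (np > nt) return(character(0))
  tkey <- paste(
    pmin(target$edges$from, target$edges$to),
    pmax(target$edges$from, target$edges$to)
  )
  tlab <- stats::setNames(target$edges$label, tkey)
  pf <- match(pattern$edges$from, pattern$nodes$id)
  pt <- match(pattern$edges$to, pattern$nodes$id)
  sigs <- character(0)
  assign_next <- function(map) {
    pos <- length(map) + 1L
    if (pos > np) {
      ok <- TRUE
      for (k in seq_along(pf)) {
        a <- target$nodes$id[map[pf[k]]]
        b <- target$nodes$id[map[pt[k]]]
        lab <- tlab[paste(min(a, b), max(a, b))]
        if (is.na(lab) || !oracle_compatible(pattern$edges$label[k], lab)) {
          ok <- FALSE
          break
        }
      }
      if (ok) sigs <<- c(sigs, paste(target$nodes$id[map], collapse = ","))
      return(invisible())
    }
    for (cand in seq_len(nt)) {
      if (cand %in% map) next
      if (!oracle_compatible(pattern$nodes$label[pos], target$nodes$label[cand])) next
      assign_next(c(map, cand))
    }
    invisible()
  }
  assign_next(integer(0))
  sort(unique(sigs))
}

# signatures of a map_pattern() result, comparable to oracle_embeddings()
mapping_signatures <- function(mappings, pattern) {
  if (nrow(mappings) == 0) return(character(0))
  sort(vapply(mappings$node_map, function(nm) {
    paste(nm$target_id[match(sort(pattern$nodes$id), nm$pattern_node)],
      collapse = ","
    )
  }, character(1)))
}

# ---- rank-selection oracle -----------------------------------------------

# smallest d with a >= threshold variance fraction, via eigen(X'X)
oracle_select_rank <- function(x, threshold) {
  ev <- eigen(crossprod(x), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev <- ev[ev > max(ev) * 1e-12]
  frac <- cumsum(ev) / sum(ev)
  which(frac >= threshold - 1e-12)[1]
}

# ---- connectivity oracle -------------------------------------------------

.adj_connected_oracle <- function(adj) {
  igraph::is_connected(
    igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
  )
}

# ---- shared synthetic atoms ----------------------------------------------

# minimal labeled atom table for compute_contacts(): one P/I pair at a
# given distance along x, offset so multiple pairs never interact
synthetic_pair_atoms <- function(label_p, label_i, distance, offset = 0) {
  tibble::tibble(
    atom_id = c(1L, 2L) + 2L * as.integer(offset),
    side = c("P", "I"),
    label = c(label_p, label_i),
    x = c(offset * 1000, offset * 1000 + distance),
    y = 0,
    z = 0
  )
}
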