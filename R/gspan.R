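#' @title Frequent subgraph mining with gSpan
#' @description
#' The miner enumerates connected labeled subgraph patterns by depth-first
#' code growth. Every pattern is identified by its minimum DFS code — the
#' lexicographically smallest sequence of edge tuples
#' `(i, j, l_i, l_e, l_j)` over all depth-first traversals of the pattern —
#' which makes the enumeration duplicate-free: a search branch whose code is
#' not minimal is pruned, because the same pattern is reached through its
#' minimal code elsewhere. Support is transaction-based: the number of
#' distinct dataset graphs containing the pattern, regardless of how many
#' embeddings each graph holds.
#' @name gspan
NULL

# ---- internal graph form -------------------------------------------------

# Convert a simple_graph to the miner's internal form: vertex labels,
# edge table, and adjacency lists of (edge index, neighbor).
.mg <- function(g) {
  stopifnot(inherits(g, "simple_graph"))
  n <- nrow(g$nodes)
  vlab <- g$nodes$label
  ef <- match(g$edges$from, g$nodes$id)
  et <- match(g$edges$to, g$nodes$id)
  adj <- vector("list", n)
  for (k in seq_along(ef)) {
    adj[[ef[k]]] <- rbind(adj[[ef[k]]], c(k, et[k]))
    adj[[et[k]]] <- rbind(adj[[et[k]]], c(k, ef[k]))
  }
  list(
    n = n, vlab = vlab,
    eu = ef, ev = et, elab = g$edges$label,
    adj = adj, ids = g$nodes$id
  )
}

# ---- DFS-code ordering ---------------------------------------------------

# A tuple is list(i, j, li, le, lj); forward iff i < j.
# Returns TRUE iff a < b in gSpan's DFS-code edge order.
.tuple_less <- function(a, b) {
  fa <- a$i < a$j
  fb <- b$i < b$j
  if (fa && fb) {
    if (a$j != b$j) return(a$j < b$j)
    if (a$i != b$i) return(a$i > b$i)
  } else if (!fa && !fb) {
    if (a$i != b$i) return(a$i < b$i)
    if (a$j != b$j) return(a$j < b$j)
  } else if (!fa && fb) {
    return(a$i < b$j)
  } else {
    return(a$j <= b$i)
  }
  # same (i, j) shape: compare labels lexicographically
  la <- c(a$li, a$le, a$lj)
  lb <- c(b$li, b$le, b$lj)
  for (t in 1:3) {
    if (la[t] != lb[t]) return(la[t] < lb[t])
  }
  FALSE
}

.tuple_equal <- function(a, b) {
  a$i == b$i && a$j == b$j && a$li == b$li && a$le == b$le && a$lj == b$lj
}

.tuple_key <- function(t) {
  paste(t$i, t$j, t$li, t$le, t$lj, sep = "\r")
}

# serialize a code (list of tuples) to a display string
.code_string <- function(code) {
  paste(
    vapply(
      code,
      function(t) sprintf("(%d,%d,%s,%s,%s)", t$i - 1L, t$j - 1L, t$li, t$le, t$lj),
      character(1)
    ),
    collapse = ";"
  )
}

# vertex labels and rightmost path implied by a code
.code_vlabels <- function(code) {
  lab <- character(0)
  for (t in code) {
    if (t$i > t$j) next
    lab[t$i] <- t$li
    lab[t$j] <- t$lj
  }
  lab
}

.rightmost_path <- function(code) {
  parent <- integer(0)
  vmax <- 1L
  for (t in code) {
    if (t$i < t$j) {
      parent[t$j] <- t$i
      vmax <- max(vmax, t$j)
    }
  }
  path <- vmax
  while (path[1] != 1L) path <- c(parent[path[1]], path)
  path # root ... rightmost vertex
}

# edges already present in the code, as "i:j" keys with i < j in code space
.code_edge_keys <- function(code) {
  vapply(
    code,
    function(t) paste(min(t$i, t$j), max(t$i, t$j), sep = ":"),
    character(1)
  )
}

# ---- extension enumeration ----------------------------------------------

# Enumerate the gSpan rightmost-path extensions of one embedding.
# emb: list(gid, vmap = graph vertices indexed by code vertex, eset = used
# graph edge indices). Returns list of list(tuple, vertex, eid) where vertex
# is the mapped graph vertex of the new code vertex (forward) or NA
# (backward).
.extensions <- function(code, emb, graph) {
  vlab <- .code_vlabels(code)
  rmp <- .rightmost_path(code)
  vr <- rmp[length(rmp)]
  nv <- length(vlab)
  present <- .code_edge_keys(code)
  out <- list()
  gvr <- emb$vmap[vr]
  # backward: from the rightmost vertex to a rightmost-path vertex
  a <- graph$adj[[gvr]]
  if (!is.null(a)) {
    for (r in seq_len(nrow(a))) {
      eid <- a[r, 1]
      if (eid %in% emb$eset) next
      w <- a[r, 2]
      j <- match(w, emb$vmap)
      if (!is.na(j) && j %in% rmp && j != vr) {
        key <- paste(min(vr, j), max(vr, j), sep = ":")
        if (!key %in% present) {
          out[[length(out) + 1]] <- list(
            tuple = list(i = vr, j = j, li = vlab[vr], le = graph$elab[eid], lj = vlab[j]),
            vertex = NA_integer_, eid = eid
          )
        }
      }
    }
  }
  # forward: from any rightmost-path vertex to an unmapped graph vertex
  for (u in rmp) {
    gu <- emb$vmap[u]
    a <- graph$adj[[gu]]
    if (is.null(a)) next
    for (r in seq_len(nrow(a))) {
      eid <- a[r, 1]
      if (eid %in% emb$eset) next
      w <- a[r, 2]
      if (w %in% emb$vmap) next
      out[[length(out) + 1]] <- list(
        tuple = list(
          i = u, j = nv + 1L, li = vlab[u],
          le = graph$elab[eid], lj = graph$vlab[w]
        ),
        vertex = w, eid = eid
      )
    }
  }
  out
}

# ---- minimum DFS code ----------------------------------------------------

#' Minimum DFS code of a connected labeled simple graph
#'
#' Computes the canonical minimum DFS code by greedy construction: at every
#' step, over all surviving partial depth-first embeddings of the graph into
#' itself, the lexicographically smallest admissible extension tuple is
#' chosen and only embeddings realizing it are kept. Re-encoding the same
#' graph from any vertex permutation yields an identical code.
#'
#' @param g a connected `simple_graph` with at least one edge.
#' @return A string serialization of the minimum DFS code.
#' @export
min_dfs_code <- function(g) {
  graph <- if (inherits(g, "simple_graph")) .mg(g) else g
  if (length(graph$elab) == 0) stop("minimum DFS code requires at least one edge")
  ne <- length(graph$elab)
  # start: minimal (li, le, lj) over all oriented edges
  starts <- list()
  for (k in seq_len(ne)) {
    for (ori in 1:2) {
      u <- if (ori == 1) graph$eu[k] else graph$ev[k]
      v <- if (ori == 1) graph$ev[k] else graph$eu[k]
      starts[[length(starts) + 1]] <- list(
        tuple = list(i = 1L, j = 2L, li = graph$vlab[u], le = graph$elab[k], lj = graph$vlab[v]),
        emb = list(gid = 1L, vmap = c(u, v), eset = k)
      )
    }
  }
  best <- NULL
  for (s in starts) {
    if (is.null(best) || .tuple_less(s$tuple, best)) best <- s$tuple
  }
  code <- list(best)
  embs <- list()
  for (s in starts) {
    if (.tuple_equal(s$tuple, best)) embs[[length(embs) + 1]] <- s$emb
  }
  while (length(code) < ne) {
    cand_best <- NULL
    nexts <- list()
    for (emb in embs) {
      for (ext in .extensions(code, emb, graph)) {
        if (is.null(cand_best) || .tuple_less(ext$tuple, cand_best)) {
          cand_best <- ext$tuple
        }
        nexts[[length(nexts) + 1]] <- list(ext = ext, emb = emb)
      }
    }
    if (is.null(cand_best)) stop("graph is not connected")
    new_embs <- list()
    for (ne_ in nexts) {
      if (.tuple_equal(ne_$ext$tuple, cand_best)) {
        emb <- ne_$emb
        if (!is.na(ne_$ext$vertex)) emb$vmap <- c(emb$vmap, ne_$ext$vertex)
        emb$eset <- c(emb$eset, ne_$ext$eid)
        new_embs[[length(new_embs) + 1]] <- emb
      }
    }
    code[[length(code) + 1]] <- cand_best
    embs <- new_embs
  }
  .code_string(code)
}

# is the (list-form) code minimal for the pattern graph it encodes?
.is_min_code <- function(code, pattern_graph) {
  identical(.code_string(code), min_dfs_code(pattern_graph))
}

# build a simple_graph from a (list-form) DFS code
.code_to_graph <- function(code) {
  vlab <- .code_vlabels(code)
  from <- integer(0); to <- integer(0); elab <- character(0)
  for (t in code) {
    from <- c(from, t$i)
    to <- c(to, t$j)
    elab <- c(elab, t$le)
  }
  make_simple_graph(
    nodes = tibble::tibble(id = seq_along(vlab), label = vlab),
    edges = tibble::tibble(from = from, to = to, label = elab)
  )
}

# ---- mining --------------------------------------------------------------

#' Mine frequent connected subgraphs from a set of labeled graphs
#'
#' Runs gSpan over a cluster of labeled simple graphs and returns every
#' connected pattern with at least one edge occurring in at least
#' `ceiling(min_support * length(graphs))` distinct graphs. Node and edge
#' labels are compared by exact string equality.
#'
#' @param graphs a list of `simple_graph` objects (or `interface_graph`s,
#'   converted via [to_simple_graph()]).
#' @param min_support minimum support as a fraction in `(0, 1]`.
#' @param max_pattern_nodes optional cap on pattern size in nodes.
#' @return A tibble with one row per frequent pattern: `pattern_id`,
#'   `dfs_code`, `n_nodes`, `n_edges`, `support_count`, `support_fraction`,
#'   `occurrences` (list of 0-based graph indices, or the dataset's own ids
#'   when the list is named), and a `graph` list-column of `simple_graph`
#'   patterns.
#' @export
gspan <- function(graphs, min_support, max_pattern_nodes = Inf) {
  if (length(graphs) == 0) stop("empty graph cluster")
  if (min_support <= 0 || min_support > 1) stop("min_support must lie in (0, 1]")
  graphs <- lapply(graphs, function(g) {
    if (inherits(g, "interface_graph")) to_simple_graph(g) else g
  })
  gids <- names(graphs)
  if (is.null(gids)) gids <- as.character(seq_along(graphs) - 1L)
  mgs <- lapply(graphs, .mg)
  nG <- length(mgs)
  minsup <- ceiling(min_support * nG - 1e-9)

  results <- new.env(parent = emptyenv())
  results$rows <- list()

  report <- function(code, embs) {
    gset <- sort(unique(vapply(embs, function(e) e$gid, integer(1))))
    pg <- .code_to_graph(code)
    results$rows[[length(results$rows) + 1]] <- tibble::tibble(
      dfs_code = .code_string(code),
      n_nodes = nrow(pg$nodes),
      n_edges = nrow(pg$edges),
      support_count = length(gset),
      support_fraction = length(gset) / nG,
      occurrences = list(gids[gset]),
      graph = list(pg)
    )
  }

  grow <- function(code, embs) {
    pg <- .code_to_graph(code)
    if (!.is_min_code(code, pg)) return(invisible())
    report(code, embs)
    # gather extensions grouped by tuple; at the node cap only backward
    # closures (which add no vertex) are admitted
    groups <- new.env(parent = emptyenv())
    order_keys <- character(0)
    tuples <- list()
    for (emb in embs) {
      for (ext in .extensions(code, emb, mgs[[emb$gid]])) {
        if (!is.na(ext$vertex) && length(.code_vlabels(code)) >= max_pattern_nodes) next
        key <- .tuple_key(ext$tuple)
        if (is.null(groups[[key]])) {
          groups[[key]] <- list()
          order_keys <- c(order_keys, key)
          tuples[[key]] <- ext$tuple
        }
        emb2 <- emb
        if (!is.na(ext$vertex)) emb2$vmap <- c(emb2$vmap, ext$vertex)
        emb2$eset <- c(emb2$eset, ext$eid)
        groups[[key]] <- c(groups[[key]], list(emb2))
      }
    }
    if (length(order_keys) == 0) return(invisible())
    # recurse in canonical tuple order
    ord <- order_keys[.order_tuples(lapply(order_keys, function(k) tuples[[k]]))]
    for (key in ord) {
      embs2 <- groups[[key]]
      sup <- length(unique(vapply(embs2, function(e) e$gid, integer(1))))
      if (sup < minsup) next
      grow(c(code, list(tuples[[key]])), embs2)
    }
    invisible()
  }

  # frequent 1-edge starts
  starts <- new.env(parent = emptyenv())
  start_keys <- character(0)
  start_tuples <- list()
  for (gi in seq_len(nG)) {
    mg <- mgs[[gi]]
    for (k in seq_along(mg$elab)) {
      for (ori in 1:2) {
        u <- if (ori == 1) mg$eu[k] else mg$ev[k]
        v <- if (ori == 1) mg$ev[k] else mg$eu[k]
        if (mg$vlab[u] > mg$vlab[v]) next # canonical start has li <= lj
        tup <- list(i = 1L, j = 2L, li = mg$vlab[u], le = mg$elab[k], lj = mg$vlab[v])
        key <- .tuple_key(tup)
        if (is.null(starts[[key]])) {
          starts[[key]] <- list()
          start_keys <- c(start_keys, key)
          start_tuples[[key]] <- tup
        }
        starts[[key]] <- c(
          starts[[key]],
          list(list(gid = gi, vmap = c(u, v), eset = k))
        )
      }
    }
  }
  ord <- start_keys[.order_tuples(lapply(start_keys, function(k) start_tuples[[k]]))]
  for (key in ord) {
    embs <- starts[[key]]
    sup <- length(unique(vapply(embs, function(e) e$gid, integer(1))))
    if (sup < minsup) next
    grow(list(start_tuples[[key]]), embs)
  }

  rows <- results$rows
  if (length(rows) == 0) {
    return(tibble::tibble(
      pattern_id = integer(0), dfs_code = character(0), n_nodes = integer(0),
      n_edges = integer(0), support_count = integer(0),
      support_fraction = numeric(0), occurrences = list(), graph = list()
    ))
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$n_edges, .data$dfs_code)
  out$pattern_id <- seq_len(nrow(out)) - 1L
  dplyr::relocate(out, "pattern_id")
}

# order indices of a list of tuples under .tuple_less (insertion sort; the
# candidate lists are short)
.order_tuples <- function(tuples) {
  n <- length(tuples)
  idx <- seq_len(n)
  if (n < 2) return(idx)
  for (a in 2:n) {
    key <- idx[a]
    b <- a - 1
    while (b >= 1 && .tuple_less(tuples[[key]], tuples[[idx[b]]])) {
      idx[b + 1] <- idx[b]
      b <- b - 1
    }
    idx[b + 1] <- key
  }
  idx
}
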