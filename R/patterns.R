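#' Subgraph containment between labeled simple graphs
#'
#' Backtracking search for an injective node map of `small` into `big` such
#' that every edge of `small` maps onto an edge of `big` with compatible
#' labels (non-induced subgraph isomorphism). Label comparison is exact
#' string equality by default, or the symmetric subset rule
#' ([labels_compatible()]) used during pattern mapping.
#'
#' @param big,small `simple_graph` objects.
#' @param label_match `"exact"` or `"subset"`.
#' @return `TRUE` iff `small` is contained in `big`.
#' @export
sg_contains <- function(big, small, label_match = c("exact", "subset")) {
  label_match <- match.arg(label_match)
  length(.sg_embeddings(big, small, label_match, first_only = TRUE)) > 0
}

# all (or the first) injective embeddings of small into big; returns a list
# of integer vectors mapping small node position -> big node position
.sg_embeddings <- function(big, small, label_match = "exact", first_only = FALSE) {
  ns <- nrow(small$nodes)
  nb <- nrow(big$nodes)
  if (ns > nb || nrow(small$edges) > nrow(big$edges)) return(list())
  node_ok <- if (label_match == "exact") {
    function(a, b) a == b
  } else {
    function(a, b) labels_compatible(a, b)
  }
  sadj <- .adjacency(small)
  badj <- .adjacency(big)
  # edge label lookup in big, keyed on position pair
  bkey <- paste(
    pmin(match(big$edges$from, big$nodes$id), match(big$edges$to, big$nodes$id)),
    pmax(match(big$edges$from, big$nodes$id), match(big$edges$to, big$nodes$id))
  )
  belab <- stats::setNames(big$edges$label, bkey)
  sef <- match(small$edges$from, small$nodes$id)
  set_ <- match(small$edges$to, small$nodes$id)
  # order small vertices so each (after the first) touches a previous one
  ord <- integer(0)
  if (ns > 0) {
    seen <- logical(ns)
    ord <- 1L
    seen[1] <- TRUE
    while (length(ord) < ns) {
      nxt <- NA_integer_
      for (v in seq_len(ns)) {
        if (!seen[v] && length(sadj[[v]]) > 0 && any(sadj[[v]] %in% ord)) {
          nxt <- v
          break
        }
      }
      if (is.na(nxt)) nxt <- which(!seen)[1] # disconnected small graph
      seen[nxt] <- TRUE
      ord <- c(ord, nxt)
    }
  }
  st <- new.env(parent = emptyenv())
  st$found <- list()
  st$halt <- FALSE
  map <- rep(NA_integer_, ns)
  used <- logical(nb)
  bt <- function(pos) {
    if (st$halt) return()
    if (pos > ns) {
      st$found[[length(st$found) + 1]] <- map
      if (first_only) st$halt <- TRUE
      return()
    }
    v <- ord[pos]
    for (cand in seq_len(nb)) {
      if (used[cand]) next
      if (!node_ok(small$nodes$label[v], big$nodes$label[cand])) next
      ok <- TRUE
      for (k in seq_along(sef)) {
        a <- sef[k]; b <- set_[k]
        if ((a == v && !is.na(map[b])) || (b == v && !is.na(map[a]))) {
          other <- if (a == v) map[b] else map[a]
          key <- paste(min(cand, other), max(cand, other))
          bl <- belab[key]
          if (is.na(bl) ||
            (label_match == "exact" && bl != small$edges$label[k]) ||
            (label_match == "subset" && !labels_compatible(small$edges$label[k], bl))) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) next
      map[v] <<- cand
      used[cand] <<- TRUE
      bt(pos + 1)
      map[v] <<- NA_integer_
      used[cand] <<- FALSE
      if (st$halt) return()
    }
  }
  if (ns > 0) bt(1) else st$found[[1]] <- integer(0)
  st$found
}

#' Filter a pattern set to its maximal members
#'
#' A frequent pattern is maximal when it is not contained (by exact-label
#' subgraph isomorphism) in any other pattern of the same mining run. The
#' surviving set is an antichain under containment.
#'
#' @param patterns a pattern tibble from [gspan()].
#' @return The same tibble with an `is_maximal` logical column, filtered to
#'   the maximal rows (pattern ids are preserved).
#' @export
filter_maximal <- function(patterns) {
  np <- nrow(patterns)
  if (np == 0) {
    patterns$is_maximal <- logical(0)
    return(patterns)
  }
  keep <- rep(TRUE, np)
  for (a in seq_len(np)) {
    for (b in seq_len(np)) {
      if (a == b) next
      if (patterns$n_edges[a] > patterns$n_edges[b]) next
      if (patterns$dfs_code[a] == patterns$dfs_code[b]) next
      if (sg_contains(patterns$graph[[b]], patterns$graph[[a]], "exact")) {
        keep[a] <- FALSE
        break
      }
    }
  }
  out <- patterns[keep, , drop = FALSE]
  out$is_maximal <- TRUE
  out
}

#' Display labels of a mined pattern
#'
#' Restricts each pattern node's mined label set to the roles its own
#' pattern edges exercise: an aromatic-stacking edge exercises the aromatic
#' label, a hydrophobic edge the hydrophobic label, salt bridges and
#' repulsive contacts the charge labels consistent with the partner, and
#' hydrogen bonds the acceptor/donor roles orientable against the partner.
#' This reproduces the subset labels seen when patterns are presented: a
#' node mined as acceptor/negative whose only pattern edge is a salt bridge
#' displays as negative.
#'
#' @param pattern_graph a `simple_graph` pattern (node labels = mined label
#'   strings, edge labels = `/`-joined interaction types).
#' @return Character vector of canonical display-label strings, one per
#'   node (in node-table order). Nodes with no consistent role fall back to
#'   their mined label with a warning.
#' @export
derive_display_labels <- function(pattern_graph) {
  g <- pattern_graph
  n <- nrow(g$nodes)
  disp <- vector("list", n)
  ef <- match(g$edges$from, g$nodes$id)
  et <- match(g$edges$to, g$nodes$id)
  for (k in seq_along(ef)) {
    a <- ef[k]; b <- et[k]
    la <- split_label(g$nodes$label[a])
    lb <- split_label(g$nodes$label[b])
    for (ty in strsplit(g$edges$label[k], "/", fixed = TRUE)[[1]]) {
      if (!ty %in% INTERACTION_TYPES) next # synthetic alphabets: no role model
      # as.character() keeps empty results as character(0): assigning NULL
      # into a list element would delete it
      disp[[a]] <- as.character(union(disp[[a]], exercised_labels(la, lb, ty)))
      disp[[b]] <- as.character(union(disp[[b]], exercised_labels(lb, la, ty)))
    }
  }
  out <- character(n)
  for (v in seq_len(n)) {
    if (length(disp[[v]]) == 0) {
      warning(
        "no consistent role assignment for pattern node ", g$nodes$id[v],
        "; falling back to its mined label",
        call. = FALSE
      )
      out[v] <- g$nodes$label[v]
    } else {
      out[v] <- canonical_label(disp[[v]])
    }
  }
  out
}

#' Sweep the minimum-support grid over a cluster of graphs
#'
#' Runs [gspan()] plus [filter_maximal()] at each support of the grid and
#' summarizes the result; pattern counts are non-increasing in the support
#' by anti-monotonicity.
#'
#' @inheritParams gspan
#' @param grid support fractions to sweep (default 0.1 to 1.0, step 0.1).
#' @return A tibble: `support`, `n_patterns`, `n_maximal`, `max_nodes`.
#' @export
support_sweep <- function(graphs, grid = seq(0.1, 1.0, by = 0.1),
                          max_pattern_nodes = Inf) {
  if (length(grid) == 0) stop("empty support grid")
  rows <- purrr::map(grid, function(s) {
    pats <- gspan(graphs, s, max_pattern_nodes = max_pattern_nodes)
    mx <- filter_maximal(pats)
    tibble::tibble(
      support = s,
      n_patterns = nrow(pats),
      n_maximal = nrow(mx),
      max_nodes = if (nrow(pats) > 0) max(pats$n_nodes) else 0L
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("support_sweep", class(out))
  out
}
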