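#' Reference items for pattern evaluation
#'
#' A reference set lists literature-derived items a mined pattern can be
#' checked against. Each item is either a residue rule (residue name and
#' author number, optionally restricted to one side of the interface) or a
#' micro-structure rule: a small labeled graph — such as the two-donor /
#' one-acceptor hydrogen-bond arrangement of an oxyanion hole — that must
#' be subgraph-compatible with the pattern under subset-label matching.
#'
#' @param ... reference items, each a named list with an `id` and either
#'   `residue = list(resname =, resno =, side = NULL)` or
#'   `motif = <simple_graph>` (or a list with `nodes`/`edges` tables).
#' @return A `reference_set` tibble: `id`, `type`, `resname`, `resno`,
#'   `side`, `motif` (list column).
#' @export
#' @examples
#' ref <- reference_set(
#'   list(id = "II", residue = list(resname = "ASP", resno = 189)),
#'   list(id = "IV", motif = make_simple_graph(
#'     nodes = data.frame(id = 1:3, label = c("DN", "DN", "AC")),
#'     edges = data.frame(
#'       from = c(1, 2), to = c(3, 3),
#'       label = "hydrogen_bond"
#'     )
#'   ))
#' )
reference_set <- function(...) {
  items <- list(...)
  if (length(items) == 1 && is.list(items[[1]]) && is.null(items[[1]]$id)) {
    items <- items[[1]] # a plain list of items
  }
  if (length(items) == 0) stop("a reference set must contain at least one item")
  rows <- purrr::map(items, function(it) {
    stopifnot(!is.null(it$id))
    if (!is.null(it$residue)) {
      tibble::tibble(
        id = as.character(it$id), type = "residue",
        resname = it$residue$resname,
        resno = as.integer(it$residue$resno),
        side = it$residue$side %||% NA_character_,
        motif = list(NULL)
      )
    } else if (!is.null(it$motif)) {
      m <- it$motif
      if (!inherits(m, "simple_graph")) {
        m <- make_simple_graph(
          tibble::as_tibble(do.call(rbind.data.frame, m$nodes)),
          tibble::as_tibble(do.call(rbind.data.frame, m$edges))
        )
      }
      tibble::tibble(
        id = as.character(it$id), type = "motif",
        resname = NA_character_, resno = NA_integer_, side = NA_character_,
        motif = list(m)
      )
    } else {
      stop("reference item ", it$id, " needs a residue or motif rule")
    }
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$id)) stop("reference ids must be unique")
  class(out) <- c("reference_set", class(out))
  out
}

#' Read a reference set from a YAML file
#'
#' @param path YAML file: a list of items, each with `id` and either a
#'   `residue` mapping (`resname`, `resno`, optional `side`) or a `motif`
#'   mapping (`nodes`/`edges` lists of records).
#' @return A `reference_set` tibble.
#' @export
read_reference_set <- function(path) {
  reference_set(yaml::read_yaml(path))
}

#' Reference items matched by each pattern
#'
#' A residue rule matches a pattern when any of the pattern's verified
#' mappings touches that residue; a micro-structure rule matches when the
#' rule's labeled graph is subgraph-compatible with the pattern itself
#' (subset-label matching, the same rule the mapper uses).
#'
#' @param patterns a pattern tibble ([gspan()] / [filter_maximal()]).
#' @param mappings a mapping table from [map_all()] over those patterns.
#' @param ref a `reference_set`.
#' @return A tibble `pattern_id`, `matched` (list of matched reference ids).
#' @export
pattern_relevance <- function(patterns, mappings, ref) {
  if (nrow(ref) == 0) stop("empty reference set")
  res <- pattern_residues(mappings)
  sides <- NULL
  if (nrow(mappings) > 0 && "target_side" %in% names(mappings$node_map[[1]])) {
    sides <- mappings |>
      dplyr::mutate(res = purrr::map(.data$node_map, function(nm) {
        dplyr::distinct(nm[, c("target_resname", "target_resno", "target_side")])
      })) |>
      dplyr::select("pattern_id", "res") |>
      tidyr::unnest("res") |>
      dplyr::distinct()
  }
  matched <- purrr::map(patterns$pattern_id, function(pid) {
    hits <- character(0)
    pres <- dplyr::filter(res, .data$pattern_id == pid)
    for (k in seq_len(nrow(ref))) {
      if (ref$type[k] == "residue") {
        ok <- any(pres$resname == ref$resname[k] & pres$resno == ref$resno[k])
        if (ok && !is.na(ref$side[k]) && !is.null(sides)) {
          ok <- any(
            sides$pattern_id == pid &
              sides$target_resname == ref$resname[k] &
              sides$target_resno == ref$resno[k] &
              sides$target_side == ref$side[k]
          )
        }
        if (ok) hits <- c(hits, ref$id[k])
      } else {
        pg <- patterns$graph[[match(pid, patterns$pattern_id)]]
        if (length(.sg_embeddings(pg, ref$motif[[k]], "subset", first_only = TRUE)) > 0) {
          hits <- c(hits, ref$id[k])
        }
      }
    }
    hits
  })
  tibble::tibble(pattern_id = patterns$pattern_id, matched = matched)
}

#' Precision and recall of mined patterns against a reference set
#'
#' A pattern is relevant when it matches at least one reference item.
#' Per-group precision is the fraction of the group's patterns that are
#' relevant; per-group recall is the fraction of reference items matched by
#' the group's patterns. The overall row pools all patterns: its precision
#' is total-relevant / total-patterns and its recall the fraction of
#' reference items matched anywhere.
#'
#' @param relevance a tibble with columns `group`, `pattern_id` and
#'   `matched` (list of matched reference ids per pattern), e.g. a grouped
#'   binding of [pattern_relevance()] results.
#' @param ref the `reference_set` evaluated against.
#' @param digits rounding of the reported ratios (default 2).
#' @return An `evaluation_report` tibble with one row per group plus an
#'   `"All"` row: `group`, `patterns`, `precision`, `recall`, `residues`.
#' @export
precision_recall <- function(relevance, ref, digits = 2) {
  stopifnot(all(c("group", "pattern_id", "matched") %in% names(relevance)))
  if (nrow(relevance) == 0) stop("no patterns to evaluate")
  n_ref <- nrow(ref)
  per_group <- relevance |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      patterns = dplyr::n(),
      relevant = sum(lengths(.data$matched) > 0),
      ids = list(sort(unique(unlist(.data$matched)))),
      .groups = "drop"
    )
  overall <- tibble::tibble(
    group = "All",
    patterns = sum(per_group$patterns),
    relevant = sum(per_group$relevant),
    ids = list(sort(unique(unlist(per_group$ids))))
  )
  out <- dplyr::bind_rows(
    dplyr::mutate(per_group, group = as.character(.data$group)), overall
  )
  out <- dplyr::mutate(
    out,
    precision = round(.data$relevant / .data$patterns, digits),
    recall = round(lengths(.data$ids) / n_ref, digits),
    residues = vapply(
      .data$ids, function(x) paste(x, collapse = ","), character(1)
    )
  )
  out <- dplyr::select(
    out, "group", "patterns", "precision", "recall", "residues"
  )
  class(out) <- c("evaluation_report", class(out))
  out
}
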