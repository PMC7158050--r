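#' Distance criteria for interface contacts
#'
#' Returns the distance windows (in Angstrom, closed intervals) used to type
#' non-covalent cross-chain contacts. A pair of atoms at distance `dist`
#' forms an edge of a given interaction type when `min <= dist <= max` and
#' the endpoint labels satisfy the type's condition:
#'
#' | type                | condition                         | min | max |
#' |---------------------|-----------------------------------|-----|-----|
#' | `aromatic_stacking` | two aromatic atoms                | 1.5 | 3.5 |
#' | `hydrogen_bond`     | one acceptor and one donor        | 2.0 | 3.0 |
#' | `hydrophobic`       | two hydrophobic atoms             | 2.0 | 3.8 |
#' | `repulsive`         | two atoms with the same charge    | 2.0 | 6.0 |
#' | `salt_bridge`       | two atoms with opposite charge    | 2.0 | 6.0 |
#'
#' @param overrides optional named list of `c(min, max)` numeric pairs to
#'   replace individual windows, e.g. `list(hydrogen_bond = c(2.0, 3.2))`.
#' @return A tibble with columns `type`, `min`, `max`.
#' @export
contact_criteria <- function(overrides = NULL) {
  crit <- tibble::tibble(
    type = c(
      "aromatic_stacking", "hydrogen_bond", "hydrophobic",
      "repulsive", "salt_bridge"
    ),
    min = c(1.5, 2.0, 2.0, 2.0, 2.0),
    max = c(3.5, 3.0, 3.8, 6.0, 6.0)
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% crit$type) stop("unknown interaction type: ", nm)
      v <- as.numeric(overrides[[nm]])
      stopifnot(length(v) == 2)
      crit$min[crit$type == nm] <- v[1]
      crit$max[crit$type == nm] <- v[2]
    }
  }
  if (any(crit$min >= crit$max)) stop("criteria require min < max for every type")
  crit
}

INTERACTION_TYPES <- c(
  "aromatic_stacking", "hydrogen_bond", "hydrophobic", "repulsive",
  "salt_bridge"
)

# Does a pair with label sets (short codes) satisfy the label condition of a
# type? Returns a logical vector over pairs; la/lb are lists of code vectors.
.pair_condition <- function(type, has_a, has_b) {
  switch(type,
    aromatic_stacking = has_a[, "AR"] & has_b[, "AR"],
    hydrogen_bond = (has_a[, "AC"] & has_b[, "DN"]) | (has_a[, "DN"] & has_b[, "AC"]),
    hydrophobic = has_a[, "HB"] & has_b[, "HB"],
    repulsive = (has_a[, "NG"] & has_b[, "NG"]) | (has_a[, "PS"] & has_b[, "PS"]),
    salt_bridge = (has_a[, "NG"] & has_b[, "PS"]) | (has_a[, "PS"] & has_b[, "NG"]),
    stop("unknown interaction type: ", type)
  )
}

# Which of a node's labels does an edge of the given type exercise, given the
# partner's labels? Both arguments are short-code character vectors.
exercised_labels <- function(labels, partner, type) {
  switch(type,
    aromatic_stacking = if ("AR" %in% labels && "AR" %in% partner) "AR" else character(0),
    hydrogen_bond = c(
      if ("AC" %in% labels && "DN" %in% partner) "AC",
      if ("DN" %in% labels && "AC" %in% partner) "DN"
    ),
    hydrophobic = if ("HB" %in% labels && "HB" %in% partner) "HB" else character(0),
    repulsive = intersect(intersect(c("NG", "PS"), labels), partner),
    salt_bridge = c(
      if ("NG" %in% labels && "PS" %in% partner) "NG",
      if ("PS" %in% labels && "NG" %in% partner) "PS"
    ),
    stop("unknown interaction type: ", type)
  )
}

.label_matrix <- function(labels) {
  sets <- lapply(labels, split_label)
  m <- sapply(.SHORT_CODES, function(code) {
    vapply(sets, function(s) code %in% s, logical(1))
  })
  m <- matrix(as.logical(m), nrow = length(labels), ncol = length(.SHORT_CODES))
  colnames(m) <- .SHORT_CODES
  m
}

#' Compute typed cross-chain contacts
#'
#' Emits one edge per unordered cross-side atom pair and interaction type
#' whose label condition and closed distance window (see
#' [contact_criteria()]) are both satisfied. A pair of atoms may yield
#' several parallel edges of different types (e.g. an acceptor/negative
#' oxygen at 2.8 Angstrom from a donor/positive nitrogen forms both a
#' hydrogen bond and a salt bridge); no edge ever joins two atoms on the
#' same side.
#'
#' @param atoms a labeled atom tibble from [assign_atom_labels()], with
#'   `atom_id`, `side`, `label` and coordinate columns.
#' @param criteria a criteria tibble from [contact_criteria()].
#' @return A tibble of edges: `from`, `to` (atom ids, `from` on side P),
#'   `type`, `distance`.
#' @export
compute_contacts <- function(atoms, criteria = contact_criteria()) {
  stopifnot(all(c("atom_id", "side", "label", "x", "y", "z") %in% names(atoms)))
  p <- dplyr::filter(atoms, .data$side == "P", .data$label != "")
  i <- dplyr::filter(atoms, .data$side == "I", .data$label != "")
  empty <- tibble::tibble(
    from = integer(0), to = integer(0), type = character(0),
    distance = numeric(0)
  )
  if (nrow(p) == 0 || nrow(i) == 0) return(empty)

  dx <- outer(p$x, i$x, "-")
  dy <- outer(p$y, i$y, "-")
  dz <- outer(p$z, i$z, "-")
  dist <- sqrt(dx^2 + dy^2 + dz^2)

  # prefilter pairs within the widest window
  rmax <- max(criteria$max)
  idx <- which(dist <= rmax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)

  lp <- .label_matrix(p$label)[idx[, 1], , drop = FALSE]
  li <- .label_matrix(i$label)[idx[, 2], , drop = FALSE]
  d <- dist[idx]

  out <- lapply(seq_len(nrow(criteria)), function(k) {
    type <- criteria$type[k]
    ok <- .pair_condition(type, lp, li) &
      d >= criteria$min[k] & d <= criteria$max[k]
    tibble::tibble(
      from = p$atom_id[idx[ok, 1]],
      to = i$atom_id[idx[ok, 2]],
      type = type,
      distance = d[ok]
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$from, .data$to, .data$type)
}
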