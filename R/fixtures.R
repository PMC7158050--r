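#' Generate a toy PDB complex with planted cross-chain interactions
#'
#' Writes a deterministic PDB-format text for a two-chain complex in which
#' each requested interaction is planted as an isolated atom pair at an
#' exact target distance, surrounded by decoy atoms placed far outside the
#' largest contact cutoff. Atom and residue names are taken from the real
#' typing table so labeling is exercised authentically; geometry is a
#' jittered lattice with no physical plausibility claimed. The generator
#' verifies, against the distance criteria, that each planted pair implies
#' exactly its planted interaction types (and that near-miss pairs imply
#' none), so running the interface-graph stage on the output recovers
#' exactly the planted edges.
#'
#' @param planted a data frame with columns `res_p`, `atom_p`, `res_i`,
#'   `atom_i`, `type`, `distance` and optional logical `near_miss`; each
#'   row plants one atom pair (chain P residue/atom vs chain I
#'   residue/atom) at `distance` Angstrom. `type` may join several types
#'   with `"/"` when a pair legitimately forms parallel edges.
#' @param seed RNG seed controlling decoy jitter.
#' @param complex_id identifier used in the manifest.
#' @param chains two chain letters, P side first.
#' @param n_decoys decoy atoms per chain (hydrophobic CA atoms placed
#'   > 6 Angstrom from everything on the other chain).
#' @param criteria contact criteria used for self-validation.
#' @return A list: `pdb` (character vector of PDB lines), `manifest` (list
#'   with the planted edges and decoy count).
#' @export
generate_complex_fixture <- function(planted, seed = 1, complex_id = "toy",
                                     chains = c("A", "B"), n_decoys = 4,
                                     criteria = contact_criteria()) {
  set.seed(seed)
  planted <- tibble::as_tibble(planted)
  if (!"near_miss" %in% names(planted)) planted$near_miss <- FALSE
  typing <- default_typing_table()
  lab_of <- function(res, atom) {
    hit <- typing$label[typing$resname == res & typing$atom == atom]
    if (length(hit) != 1) stop("atom ", res, " ", atom, " not in typing table")
    hit
  }
  implied_types <- function(la, lb, dist) {
    ha <- .label_matrix(la)
    hb <- .label_matrix(lb)
    ok <- vapply(seq_len(nrow(criteria)), function(k) {
      .pair_condition(criteria$type[k], ha, hb) &&
        dist >= criteria$min[k] && dist <= criteria$max[k]
    }, logical(1))
    criteria$type[ok]
  }
  # validate every planted row
  for (r in seq_len(nrow(planted))) {
    la <- lab_of(planted$res_p[r], planted$atom_p[r])
    lb <- lab_of(planted$res_i[r], planted$atom_i[r])
    got <- implied_types(la, lb, planted$distance[r])
    want <- if (planted$near_miss[r]) {
      character(0)
    } else {
      sort(strsplit(planted$type[r], "/", fixed = TRUE)[[1]])
    }
    if (!identical(sort(got), want)) {
      stop(
        "planted pair ", r, " (", planted$res_p[r], " ", planted$atom_p[r],
        " - ", planted$res_i[r], " ", planted$atom_i[r], " at ",
        planted$distance[r], " A) implies types {",
        paste(got, collapse = ", "), "} but the spec says {",
        paste(want, collapse = ", "), "}"
      )
    }
  }

  lines <- character(0)
  serial <- 0L
  atom_line <- function(name, resname, chain, resno, x, y, z, element) {
    serial <<- serial + 1L
    nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf(
      "ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, nm, resname, chain, resno, x, y, z, 1.00, 0.00, element
    )
  }
  elem <- function(atom) substr(sub("^[0-9]+", "", atom), 1, 1)
  # planted pockets, 25 A apart along x
  for (r in seq_len(nrow(planted))) {
    cx <- 25 * r
    lines <- c(
      lines,
      atom_line(
        planted$atom_p[r], planted$res_p[r], chains[1], r,
        cx, 0, 0, elem(planted$atom_p[r])
      ),
      atom_line(
        planted$atom_i[r], planted$res_i[r], chains[2], r,
        cx + planted$distance[r], 0, 0, elem(planted$atom_i[r])
      )
    )
  }
  # decoys: hydrophobic alanine CA atoms on a jittered lattice, one shelf
  # per chain, far from all cross-chain atoms
  base <- nrow(planted)
  for (j in seq_len(n_decoys)) {
    lines <- c(
      lines,
      atom_line(
        "CA", "ALA", chains[1], base + j,
        25 * j + stats::runif(1, -1, 1), 100 + stats::runif(1, -1, 1), 0, "C"
      ),
      atom_line(
        "CA", "ALA", chains[2], base + j,
        25 * j + stats::runif(1, -1, 1), 200 + stats::runif(1, -1, 1), 0, "C"
      )
    )
  }
  lines <- c(lines, "END")
  manifest <- list(
    complex_id = complex_id,
    chains = as.list(stats::setNames(chains, c("P", "I"))),
    planted = planted[!planted$near_miss, , drop = FALSE],
    near_miss = planted[planted$near_miss, , drop = FALSE],
    n_decoys = n_decoys,
    seed = seed
  )
  list(pdb = lines, manifest = manifest)
}

#' Generate a random labeled graph dataset with a planted motif
#'
#' Produces `n_graphs` connected labeled simple graphs in which a given
#' motif is embedded verbatim in exactly `round(planted_fraction *
#' n_graphs)` of them; the remaining graphs, and all noise nodes and edges,
#' are rejection-sampled so that no accidental extra copy of the motif
#' arises anywhere (checked with the exact-label containment matcher).
#'
#' @param motif a connected `simple_graph` to plant.
#' @param n_graphs number of dataset graphs.
#' @param planted_fraction fraction of graphs containing the motif;
#'   `planted_fraction * n_graphs` must be an integer.
#' @param n_noise_nodes,n_noise_edges noise nodes/extra edges per graph.
#' @param node_labels,edge_labels label alphabets for noise.
#' @param seed RNG seed.
#' @param max_tries rejection budget per graph.
#' @return A list: `graphs` (named list of `simple_graph`, names are
#'   0-based graph ids), `manifest` (list with `planted_ids` — ids of the
#'   graphs containing the motif — and per-graph planted node ids).
#' @export
generate_graph_dataset <- function(motif, n_graphs, planted_fraction,
                                   n_noise_nodes = 2, n_noise_edges = 1,
                                   node_labels = c("AC", "DN", "HB"),
                                   edge_labels = c("hydrogen_bond", "hydrophobic"),
                                   seed = 1, max_tries = 200) {
  stopifnot(inherits(motif, "simple_graph"))
  if (!.sg_connected(motif)) stop("motif must be connected")
  n_planted <- planted_fraction * n_graphs
  if (abs(n_planted - round(n_planted)) > 1e-9) {
    stop("planted_fraction * n_graphs must be an integer")
  }
  n_planted <- as.integer(round(n_planted))
  set.seed(seed)
  planted_flags <- rep(FALSE, n_graphs)
  planted_flags[sample.int(n_graphs, n_planted)] <- TRUE

  motif_nodes <- nrow(motif$nodes)
  make_graph <- function(with_motif) {
    for (try in seq_len(max_tries)) {
      if (with_motif) {
        nodes <- tibble::tibble(
          id = seq_len(motif_nodes),
          label = motif$nodes$label[order(motif$nodes$id)]
        )
        edges <- tibble::tibble(
          from = match(motif$edges$from, sort(motif$nodes$id)),
          to = match(motif$edges$to, sort(motif$nodes$id)),
          label = motif$edges$label
        )
      } else {
        nodes <- tibble::tibble(id = 1L, label = sample(node_labels, 1))
        edges <- tibble::tibble(
          from = integer(0), to = integer(0), label = character(0)
        )
      }
      # attach noise nodes as a random tree to keep the graph connected
      for (j in seq_len(n_noise_nodes)) {
        nid <- nrow(nodes) + 1L
        anchor <- sample.int(nrow(nodes), 1)
        nodes <- dplyr::bind_rows(
          nodes, tibble::tibble(id = nid, label = sample(node_labels, 1))
        )
        edges <- dplyr::bind_rows(
          edges,
          tibble::tibble(
            from = nodes$id[anchor], to = nid,
            label = sample(edge_labels, 1)
          )
        )
      }
      # extra random noise edges
      added <- 0L
      guard <- 0L
      while (added < n_noise_edges && nrow(nodes) >= 2 && guard < 50) {
        guard <- guard + 1L
        uv <- sample(nodes$id, 2)
        key <- paste(min(uv), max(uv))
        existing <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
        if (key %in% existing) next
        edges <- dplyr::bind_rows(
          edges,
          tibble::tibble(
            from = uv[1], to = uv[2], label = sample(edge_labels, 1)
          )
        )
        added <- added + 1L
      }
      g <- make_simple_graph(nodes, edges)
      embs <- .sg_embeddings(g, motif, "exact")
      ok <- if (with_motif) {
        length(embs) > 0 &&
          all(vapply(
            embs, function(m) all(m <= motif_nodes), logical(1)
          ))
      } else {
        length(embs) == 0
      }
      if (ok) {
        return(list(graph = g, planted_nodes = if (with_motif) seq_len(motif_nodes) else integer(0)))
      }
    }
    stop(
      "rejection budget exhausted while avoiding accidental motif copies; ",
      "use sparser noise or a larger label alphabet"
    )
  }

  graphs <- vector("list", n_graphs)
  planted_nodes <- vector("list", n_graphs)
  for (i in seq_len(n_graphs)) {
    res <- make_graph(planted_flags[i])
    graphs[[i]] <- res$graph
    planted_nodes[[i]] <- res$planted_nodes
  }
  ids <- as.character(seq_len(n_graphs) - 1L)
  names(graphs) <- ids
  names(planted_nodes) <- ids
  list(
    graphs = graphs,
    manifest = list(
      planted_ids = ids[planted_flags],
      planted_fraction = planted_fraction,
      planted_nodes = planted_nodes,
      seed = seed
    )
  )
}
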