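#' Read interface atoms from a PDB file
#'
#' Parses a protein complex in PDB format (via [bio3d::read.pdb()]) and
#' returns the heavy atoms of the two chain groups that form the interface,
#' each atom tagged with the side (`"P"` or `"I"`) of the bipartition it
#' belongs to. Hydrogens, waters and HETATM records are excluded; for atoms
#' with alternate locations the highest-occupancy altloc is kept; only the
#' first model of multi-model files is read.
#'
#' @param pdb path to a PDB file, or a character string of PDB-format text
#'   (detected by embedded newlines).
#' @param chain_groups a list of two disjoint, non-empty character vectors of
#'   chain identifiers, e.g. `list(P = "E", I = "I")`. The first group is
#'   side `P`, the second side `I`.
#' @param complex_id identifier recorded with every atom; defaults to the
#'   file name without extension.
#' @return A tibble with one row per atom: `complex_id`, `chain`, `resname`,
#'   `resno`, `insert`, `atom`, `element`, `x`, `y`, `z`, `side`.
#' @export
read_interface_atoms <- function(pdb, chain_groups, complex_id = NULL) {
  stopifnot(is.list(chain_groups), length(chain_groups) == 2)
  gp <- as.character(chain_groups[[1]])
  gi <- as.character(chain_groups[[2]])
  if (length(gp) == 0 || length(gi) == 0) {
    stop("both chain groups must be non-empty")
  }
  if (length(intersect(gp, gi)) > 0) {
    stop(
      "chain groups must be disjoint; shared chain(s): ",
      paste(intersect(gp, gi), collapse = ", ")
    )
  }
  path <- pdb
  tmp <- NULL
  if (length(pdb) > 1 || grepl("\n", pdb, fixed = TRUE)) {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(if (length(pdb) > 1) pdb else strsplit(pdb, "\n")[[1]], tmp)
    path <- tmp
    on.exit(unlink(tmp), add = TRUE)
  }
  if (is.null(complex_id)) {
    complex_id <- sub("\\.[^.]*$", "", basename(path))
  }
  structure_pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- tibble::as_tibble(structure_pdb$atom)

  available <- unique(at$chain)
  wanted <- c(gp, gi)
  absent <- setdiff(wanted, available)
  if (length(absent) > 0) {
    stop(
      "chain(s) not present in structure: ", paste(absent, collapse = ", "),
      "; available chains: ", paste(available, collapse = ", ")
    )
  }

  at <- dplyr::filter(
    at,
    .data$type == "ATOM",
    .data$chain %in% wanted,
    !(.data$resid %in% c("HOH", "WAT", "DOD")),
    is.na(.data$elesy) | !(.data$elesy %in% c("H", "D"))
  )
  # drop hydrogens by atom-name convention when the element column is empty
  at <- dplyr::filter(at, !grepl("^[0-9]*H", .data$elety))

  # keep highest-occupancy altloc per atom site
  at <- at |>
    dplyr::mutate(o = ifelse(is.na(.data$o), 1, .data$o)) |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()

  out <- tibble::tibble(
    complex_id = complex_id,
    chain = at$chain,
    resname = at$resid,
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    atom = at$elety,
    element = ifelse(is.na(at$elesy), "", at$elesy),
    x = at$x, y = at$y, z = at$z,
    side = ifelse(at$chain %in% gp, "P", "I")
  )
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    stop("non-finite coordinates in ", complex_id)
  }
  out <- dplyr::arrange(
    out, .data$side, .data$chain, .data$resno, .data$insert, .data$atom
  )
  out$atom_id <- seq_len(nrow(out))
  dplyr::relocate(out, "atom_id")
}
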