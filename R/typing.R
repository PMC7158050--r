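#' Default physicochemical atom typing table
#'
#' Maps each heavy atom of the 20 standard amino-acid residues to the set of
#' physicochemical labels it can carry: acceptor (AC), aromatic (AR), donor
#' (DN), hydrophobic (HB), negative (NG), positive (PS). The assignments
#' follow standard pharmacophoric typing of protein atoms:
#'
#' * backbone amide N is a donor (except proline, whose N has no hydrogen);
#'   backbone carbonyl O is an acceptor; terminal OXT is acceptor/negative;
#' * carboxylate oxygens of ASP/GLU are acceptor/negative;
#' * the lysine ammonium NZ and the arginine guanidinium NE/NH1/NH2 are
#'   donor/positive, the guanidinium carbon CZ is positive;
#' * the histidine imidazole nitrogens ND1/NE2 are aromatic, positive, donor
#'   and acceptor (the ring is titratable near physiological pH, so both
#'   tautomeric and protonated roles are kept), its ring carbons aromatic;
#' * hydroxyls of SER/THR/TYR are acceptor/donor; amide O/N of ASN/GLN are
#'   acceptor and donor respectively;
#' * ring atoms of PHE/TYR/TRP are aromatic (TRP NE1 also donor);
#' * aliphatic/thioether carbons and sulfurs follow hydrophobic typing, with
#'   CYS SG kept as weak donor/acceptor.
#'
#' An entry with an empty label string marks an atom that is known but
#' carries no interaction role (e.g. the backbone carbonyl carbon); such
#' atoms never seed contacts. Atoms absent from the table are reported by
#' [assign_atom_labels()] with a warning and are excluded from graphs.
#'
#' @return A tibble with columns `resname`, `atom`, `label` (canonical label
#'   string, possibly `""`).
#' @seealso [assign_atom_labels()]
#' @export
default_typing_table <- function() {
  rows <- list()
  add <- function(res, atoms, labels) {
    lab <- canonical_label(labels)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      resname = res,
      atom = atoms,
      label = lab
    )
  }
  aa <- c(
    "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
  )
  # backbone
  for (res in aa) {
    if (res != "PRO") add(res, "N", "DN") else add(res, "N", character(0))
    add(res, "O", "AC")
    add(res, "C", character(0))
    add(res, "OXT", c("AC", "NG"))
    add(res, "CA", if (res == "GLY") "HB" else "HB")
  }
  # aliphatic side chains
  add("ALA", "CB", "HB")
  add("VAL", c("CB", "CG1", "CG2"), "HB")
  add("LEU", c("CB", "CG", "CD1", "CD2"), "HB")
  add("ILE", c("CB", "CG1", "CG2", "CD1"), "HB")
  add("MET", c("CB", "CG", "CE"), "HB")
  add("MET", "SD", c("AC", "HB"))
  add("CYS", "CB", "HB")
  add("CYS", "SG", c("AC", "DN"))
  add("PRO", c("CB", "CG", "CD"), "HB")
  # hydroxyls
  add("SER", "CB", "HB")
  add("SER", "OG", c("AC", "DN"))
  add("THR", c("CB", "CG2"), "HB")
  add("THR", "OG1", c("AC", "DN"))
  # amides
  add("ASN", "CB", "HB")
  add("ASN", "CG", character(0))
  add("ASN", "OD1", "AC")
  add("ASN", "ND2", "DN")
  add("GLN", c("CB", "CG"), "HB")
  add("GLN", "CD", character(0))
  add("GLN", "OE1", "AC")
  add("GLN", "NE2", "DN")
  # carboxylates
  add("ASP", "CB", "HB")
  add("ASP", "CG", character(0))
  add("ASP", c("OD1", "OD2"), c("AC", "NG"))
  add("GLU", c("CB", "CG"), "HB")
  add("GLU", "CD", character(0))
  add("GLU", c("OE1", "OE2"), c("AC", "NG"))
  # basic side chains
  add("LYS", c("CB", "CG", "CD", "CE"), "HB")
  add("LYS", "NZ", c("DN", "PS"))
  add("ARG", c("CB", "CG", "CD"), "HB")
  add("ARG", c("NE", "NH1", "NH2"), c("DN", "PS"))
  add("ARG", "CZ", "PS")
  # aromatics
  add("PHE", "CB", "HB")
  add("PHE", c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), "AR")
  add("TYR", "CB", "HB")
  add("TYR", c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), "AR")
  add("TYR", "OH", c("AC", "DN"))
  add("TRP", "CB", "HB")
  add("TRP", c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"), "AR")
  add("TRP", "NE1", c("AR", "DN"))
  add("HIS", "CB", "HB")
  add("HIS", c("CG", "CD2", "CE1"), "AR")
  add("HIS", c("ND1", "NE2"), c("AR", "PS", "DN", "AC"))

  dplyr::distinct(dplyr::bind_rows(rows), .data$resname, .data$atom, .keep_all = TRUE)
}

#' Assign physicochemical labels to atoms
#'
#' Joins a table of atoms against a typing table (by residue and atom name)
#' and attaches the full pre-pruning label set of each atom. Atoms not found
#' in the table receive an empty label set and a single summary warning; they
#' cannot seed any contact and are dropped at graph construction.
#'
#' @param atoms a tibble of atom records as produced by
#'   [read_interface_atoms()], with at least `resname` and `atom` columns.
#' @param typing_table a tibble with columns `resname`, `atom`, `label`
#'   (canonical label strings). Defaults to [default_typing_table()].
#' @return `atoms` with an added `label` column (canonical label string,
#'   `""` when the atom has no interaction role).
#' @export
assign_atom_labels <- function(atoms, typing_table = default_typing_table()) {
  stopifnot(all(c("resname", "atom") %in% names(atoms)))
  out <- dplyr::left_join(atoms, typing_table, by = c("resname", "atom"))
  unknown <- is.na(out$label)
  if (any(unknown)) {
    missing <- unique(paste(out$resname[unknown], out$atom[unknown]))
    warning(
      sprintf(
        "%d atom(s) absent from typing table (excluded from graphs): %s",
        sum(unknown), paste(utils::head(missing, 10), collapse = ", ")
      ),
      call. = FALSE
    )
    out$label[unknown] <- ""
  }
  out
}
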