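#' Physicochemical atom label codes
#'
#' Atoms on a protein-protein interface are typed by the non-covalent
#' interaction roles they can play: hydrogen-bond acceptor (`ACP`), aromatic
#' (`ARM`), hydrogen-bond donor (`DON`), hydrophobic (`HPB`), negatively
#' charged (`NEG`) and positively charged (`POS`). Throughout the package a
#' label set is serialized canonically as the sorted two-letter short codes
#' joined by `"/"`, e.g. `"AC/NG"` for an acceptor/negative carboxylate
#' oxygen.
#'
#' @return `label_codes()` returns a named character vector mapping full
#'   label names to their two-letter short codes.
#' @export
#' @examples
#' label_codes()
#' canonical_label(c("NEG", "ACP"))
label_codes <- function() {
  c(ACP = "AC", ARM = "AR", DON = "DN", HPB = "HB", NEG = "NG", POS = "PS")
}

.SHORT_CODES <- c("AC", "AR", "DN", "HB", "NG", "PS")

#' Canonical serialization of a label set
#'
#' @param labels character vector of labels, as full names (`"ACP"`) or short
#'   codes (`"AC"`), in any order and possibly with duplicates.
#' @return A single string: the sorted unique short codes joined by `"/"`.
#'   An empty input yields `""`.
#' @export
canonical_label <- function(labels) {
  if (length(labels) == 0) return("")
  codes <- label_codes()
  x <- ifelse(labels %in% names(codes), codes[labels], labels)
  bad <- setdiff(x, .SHORT_CODES)
  if (length(bad) > 0) {
    stop("unknown physicochemical label(s): ", paste(unique(bad), collapse = ", "))
  }
  paste(sort(unique(x)), collapse = "/")
}

#' Split a canonical label string back into short codes
#' @param label a canonical label string such as `"AC/NG"`.
#' @return character vector of short codes (empty for `""`).
#' @export
split_label <- function(label) {
  stopifnot(length(label) == 1)
  if (is.na(label) || label == "") return(character(0))
  strsplit(label, "/", fixed = TRUE)[[1]]
}

#' Subset-compatibility of two label sets
#'
#' Two label sets are compatible when one is a subset of the other (in either
#' direction). This is the node- and edge-label match rule used when mapping
#' mined patterns back onto interface graphs: a pattern node labeled `NG` may
#' match a graph node labeled `AC/NG`, because the pattern retains only the
#' labels its own edges exercise.
#'
#' @param a,b character vectors of labels (short codes or full names), or
#'   canonical label strings.
#' @return `TRUE` iff `a` is a subset of `b` or `b` a subset of `a`.
#' @export
#' @examples
#' labels_compatible("NG", "AC/NG")   # TRUE
#' labels_compatible("AR", "DN/HB")   # FALSE
labels_compatible <- function(a, b) {
  sa <- if (length(a) == 1 && grepl("/", a, fixed = TRUE)) split_label(a) else a
  sb <- if (length(b) == 1 && grepl("/", b, fixed = TRUE)) split_label(b) else b
  all(sa %in% sb) || all(sb %in% sa)
}
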