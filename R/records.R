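#' Construct a classified domain record
#'
#' The central data type of the pipeline: one protein domain with its
#' sequence, hierarchical classification label and optional structural
#' context.
#'
#' @param domain_id Domain identifier.
#' @param sequence Amino-acid string over the 20-letter alphabet plus `X`.
#' @param classification Dot-separated A.X.H.T.F label; at least the A and X
#'   fields must be present.
#' @param coords Optional per-residue atom table as produced by
#'   [read_structure()] (`res_index` must reference positions of `sequence`).
#' @param ss Optional per-residue secondary-structure string (8-state DSSP
#'   alphabet), same length as `sequence`.
#' @param source_chain Optional PDB id + chain the domain was extracted from.
#' @return An object of class `domain_record`.
#' @export
domain_record <- function(domain_id, sequence, classification,
                          coords = NULL, ss = NULL, source_chain = NULL) {
  stopifnot(is.character(domain_id), length(domain_id) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 1) stop("domain '", domain_id, "': empty sequence")
  letters_ <- strsplit(sequence, "")[[1]]
  if (!all(letters_ %in% AA_ALPHABET21))
    stop("domain '", domain_id, "': sequence contains symbols outside the ",
         "20-letter alphabet plus X: ",
         paste(unique(setdiff(letters_, AA_ALPHABET21)), collapse = ""))
  if (length(strsplit(classification, ".", fixed = TRUE)[[1]]) < 2)
    stop("domain '", domain_id, "': classification label '", classification,
         "' has fewer than 2 dot-separated fields")
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    if (any(coords$res_index < 1 | coords$res_index > n))
      stop("domain '", domain_id, "': coords reference residues outside ",
           "the sequence")
  }
  if (!is.null(ss) && nchar(ss) != n)
    stop("domain '", domain_id, "': ss string length != sequence length")
  structure(list(domain_id = domain_id, sequence = sequence,
                 classification = classification, coords = coords,
                 ss = ss, source_chain = source_chain),
            class = "domain_record")
}

#' @export
print.domain_record <- function(x, ...) {
  cat("<domain_record> ", x$domain_id, "  [", x$classification, "]\n",
      sep = "")
  cat("  length ", nchar(x$sequence),
      if (!is.null(x$coords)) paste0(", coords (", nrow(x$coords), " atoms)"),
      if (!is.null(x$ss)) ", ss", "\n", sep = "")
  invisible(x)
}

#' Extract the X-group (fold-level) field of a classification label
#'
#' @param label Dot-separated A.X.H.T.F label(s).
#' @return Character vector of X-group identifiers (the second field).
#' @export
xgroup_of <- function(label) {
  vapply(strsplit(label, ".", fixed = TRUE), `[`, character(1), 2L)
}

#' Extract the A-group (architecture) field of a classification label
#' @param label Dot-separated A.X.H.T.F label(s).
#' @return Character vector of A-group identifiers (the first field).
#' @export
agroup_of <- function(label) {
  vapply(strsplit(label, ".", fixed = TRUE), `[`, character(1), 1L)
}
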