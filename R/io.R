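#' Read a FASTA file of domain sequences
#'
#' Sequences are upper-cased and stop characters (`*`) are stripped; record
#' order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names are the first
#'   whitespace-delimited token of each header). An empty file yields an
#'   empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">"))
    stop("malformed FASTA header at line 1 of ", path, ": ", first)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("failed to parse FASTA ", path, ": ",
                                           conditionMessage(e)))
  seqs <- toupper(gsub("\\*", "", as.character(set)))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  setNames(unname(seqs), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

## three-letter -> one-letter codes for the 20 standard residues only;
## every nonstandard residue (MSE, MLY, ...) becomes 'X'
.aa321 <- function(resid) {
  std <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  out <- unname(std[toupper(resid)])
  out[is.na(out)] <- "X"
  out
}

#' Construct a ligand instance
#'
#' @param ligand_code 1-3 character chemical component id.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` (Angstrom).
#' @param domain_id Owning domain id (may be `NA`).
#' @return An object of class `ligand_instance`.
#' @export
ligand_instance <- function(ligand_code, atoms, domain_id = NA_character_) {
  stopifnot(is.character(ligand_code), nchar(ligand_code) >= 1,
            nchar(ligand_code) <= 3)
  atoms <- as.data.frame(atoms)
  if (nrow(atoms) < 1) stop("a ligand must have at least one atom")
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  structure(list(ligand_code = ligand_code, atoms = atoms,
                 domain_id = domain_id),
            class = "ligand_instance")
}

#' Read a single-chain domain structure from a PDB-format file
#'
#' ATOM records of the requested chain are grouped by residue in file order;
#' for residues with alternate locations only the first-listed altloc of each
#' atom is kept. HETATM records (any chain) are returned separately as
#' ligands, grouped by component code and residue number. Hydrogens are
#' retained here and ignored downstream where appropriate.
#'
#' @param path Path to a PDB-format file.
#' @param chain Chain identifier; defaults to the first chain in the file.
#' @return A list with elements `coords` (data.frame: `res_index` 1-based
#'   sequential residue index, `resname`, `atom`, `x`, `y`, `z`,
#'   `author_resno`), `sequence` (one-letter string, nonstandard residues as
#'   `X`) and `ligands` (list of [ligand_instance()]).
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  chains <- unique(at$chain[at$type == "ATOM"])
  if (is.null(chain)) chain <- chains[1]
  if (!(chain %in% chains))
    stop("chain '", chain, "' not found in ", path,
         "; available chains: ", paste(chains, collapse = ", "))
  a <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  # residue identity in file order (author numbering + insertion code)
  ins <- ifelse(is.na(a$insert), "", a$insert)
  rkey <- paste(a$resno, ins, sep = "|")
  res_index <- as.integer(factor(rkey, levels = unique(rkey)))
  # altloc: keep the first occurrence of each atom name within a residue
  keep <- !duplicated(paste(rkey, a$elety))
  a <- a[keep, , drop = FALSE]
  res_index <- res_index[keep]
  coords <- data.frame(res_index = res_index,
                       resname = a$resid,
                       atom = a$elety,
                       x = a$x, y = a$y, z = a$z,
                       author_resno = a$resno,
                       stringsAsFactors = FALSE)
  resnames <- coords$resname[!duplicated(coords$res_index)]
  sequence <- paste(.aa321(resnames), collapse = "")

  h <- at[at$type == "HETATM", , drop = FALSE]
  ligands <- list()
  if (nrow(h) > 0) {
    key <- paste(h$resid, h$chain, h$resno)
    for (k in unique(key)) {
      g <- h[key == k, , drop = FALSE]
      elem <- ifelse(is.na(g$elesy) | g$elesy == "",
                     substr(trimws(g$elety), 1, 1), trimws(g$elesy))
      ligands[[length(ligands) + 1L]] <- ligand_instance(
        ligand_code = g$resid[1],
        atoms = data.frame(element = elem, x = g$x, y = g$y, z = g$z,
                           stringsAsFactors = FALSE))
    }
  }
  list(coords = coords, sequence = sequence, ligands = ligands)
}

#' Read a domain classification table
#'
#' A TSV with at least two columns: domain id and dot-separated A.X.H.T.F
#' label. Rows whose label has fewer than two dot-separated fields are
#' rejected with a warning; duplicate domain ids are resolved last-wins with
#' a warning.
#'
#' @param path Path to the TSV (no header).
#' @return Named character vector mapping domain id to classification label.
#' @export
read_classification <- function(path) {
  if (!file.exists(path)) stop("classification file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "#", colClasses = "character")
  if (ncol(tab) < 2) stop("classification TSV needs >= 2 columns: ", path)
  ids <- tab[[1]]; labels <- tab[[2]]
  nfields <- lengths(strsplit(labels, ".", fixed = TRUE))
  bad <- nfields < 2
  if (any(bad)) {
    warning(sum(bad), " classification row(s) rejected (label with < 2 ",
            "dot-separated fields), e.g. '", labels[bad][1], "'")
    ids <- ids[!bad]; labels <- labels[!bad]
  }
  dup <- duplicated(ids, fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate domain id(s) in classification; ",
            "last occurrence wins")
    ids <- ids[!dup]; labels <- labels[!dup]
  }
  setNames(labels, ids)
}

#' Write a classification table
#' @param classification Named character vector (as from
#'   [read_classification()]).
#' @param path Output path.
#' @export
write_classification <- function(classification, path) {
  write.table(data.frame(names(classification), unname(classification)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a theme-hit table
#'
#' A header-bearing TSV with columns `theme_id`, `domain_id`, `start`, `end`,
#' `e_value`, `coverage`. On disk the residue interval is 0-based half-open;
#' in R it is converted to 1-based closed. Rows failing validation
#' (non-numeric or non-positive E-value, negative start, empty interval,
#' coverage outside \[0,1\]) are dropped with a warning naming the row.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `theme_id`, `domain_id`, `start`, `end`
#'   (1-based closed), `e_value`, `coverage`, in file order.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", colClasses = "character")
  need <- c("theme_id", "domain_id", "start", "end", "e_value", "coverage")
  if (!all(need %in% names(tab)))
    stop("hit table must have columns ", paste(need, collapse = ", "))
  start0 <- suppressWarnings(as.integer(tab$start))
  end0 <- suppressWarnings(as.integer(tab$end))
  ev <- suppressWarnings(as.numeric(tab$e_value))
  cov <- suppressWarnings(as.numeric(tab$coverage))
  bad <- is.na(start0) | is.na(end0) | is.na(ev) | is.na(cov) |
    start0 < 0 | end0 <= start0 | ev <= 0 | cov < 0 | cov > 1
  if (any(bad))
    warning(sum(bad), " hit row(s) rejected (rows ",
            paste(utils::head(which(bad), 5), collapse = ", "), " ...)")
  data.frame(theme_id = tab$theme_id[!bad],
             domain_id = tab$domain_id[!bad],
             start = start0[!bad] + 1L,
             end = end0[!bad],
             e_value = ev[!bad],
             coverage = cov[!bad],
             stringsAsFactors = FALSE)
}

#' Write a theme-hit table
#'
#' Converts the in-memory 1-based closed intervals back to the on-disk
#' 0-based half-open convention.
#'
#' @param hits data.frame as returned by [read_hits()].
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(theme_id = hits$theme_id, domain_id = hits$domain_id,
                    start = hits$start - 1L, end = hits$end,
                    e_value = hits$e_value, coverage = hits$coverage)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-domain secondary-structure strings
#'
#' A TSV (no header) with columns domain id and an 8-state DSSP-alphabet
#' string, one residue per character.
#'
#' @param path Path to the TSV.
#' @return Named character vector of secondary-structure strings.
#' @export
read_ss <- function(path) {
  if (!file.exists(path)) stop("secondary-structure file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    colClasses = "character")
  setNames(tab[[2]], tab[[1]])
}

#' Read BioLiP-style binding annotations
#'
#' A TSV (no header) with columns domain id, ligand component code and a
#' space-separated list of 1-based binding residue indices.
#'
#' @param path Path to the TSV.
#' @return List of binding annotations, each a list with `domain_id`,
#'   `ligand_code`, `residues` (sorted integer vector) and `method`
#'   (`"biolip"`).
#' @export
read_biolip <- function(path) {
  if (!file.exists(path)) stop("binding annotation file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    colClasses = "character")
  lapply(seq_len(nrow(tab)), function(i) {
    res <- sort(unique(as.integer(strsplit(trimws(tab[i, 3]), "\\s+")[[1]])))
    list(domain_id = tab[i, 1], ligand_code = tab[i, 2],
         residues = res, method = "biolip")
  })
}

#' Read a substitution matrix in NCBI text format
#'
#' Lines starting with `#` are comments; the first non-comment line lists the
#' column letters and each following row starts with its row letter.
#'
#' @param path Path to the matrix file.
#' @return Integer matrix with residue-letter dimnames.
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(cols))))
  rownames(m) <- vapply(rows, `[`, character(1), 1L)
  colnames(m) <- cols
  m
}

#' The BLOSUM62 substitution matrix shipped with the package
#'
#' Parsed once from the NCBI-format text file under `inst/extdata` and
#' cached.
#'
#' @return Integer matrix over the 20 amino acids plus `X`.
#' @export
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "bridgethemes")
    .pkg_cache$blosum62 <- read_score_matrix(path)
  }
  .pkg_cache$blosum62
}
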