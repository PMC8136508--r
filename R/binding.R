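#' Default ligand exclusion list
#'
#' Component codes ignored by the binding analysis: water and unknowns,
#' common crystallographic additives, and modified amino-acid residues. The
#' list ships as a plain-text file (one code per line, `#` comments) under
#' `inst/extdata` and can be extended or replaced by the user.
#'
#' @param path Optional path to an exclusion file; default the shipped one.
#' @return Character vector of excluded component codes.
#' @export
default_ligand_exclusions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ligand_exclusions.txt",
                        package = "bridgethemes")
  lines <- trimws(readLines(path))
  toupper(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Filter ligands against an exclusion list
#'
#' @param ligands List of [ligand_instance()]s.
#' @param exclusions Character vector of component codes to drop (default
#'   [default_ligand_exclusions()]).
#' @return Filtered list.
#' @export
filter_ligands <- function(ligands, exclusions = default_ligand_exclusions()) {
  keep <- vapply(ligands, function(l)
    !(toupper(l$ligand_code) %in% toupper(exclusions)), logical(1))
  ligands[keep]
}

#' Residues binding a ligand by the distance criterion
#'
#' A residue binds the ligand when any of its (non-hydrogen) atoms lies
#' within `cutoff` Angstrom (inclusive) of any ligand atom.
#'
#' @param coords Per-residue atom table (as in [domain_record()] /
#'   [read_structure()]).
#' @param ligand A [ligand_instance()].
#' @param cutoff Distance cutoff in Angstrom (default 4.5).
#' @return Sorted integer vector of 1-based binding residue indices.
#' @export
binding_residues <- function(coords, ligand, cutoff = 4.5) {
  if (is.null(coords) || nrow(coords) == 0)
    stop("no coordinates available")
  # drop hydrogens (atom names starting with H, or nH patterns like 1H..)
  is_h <- grepl("^[0-9]?H", trimws(coords$atom))
  co <- coords[!is_h, , drop = FALSE]
  la <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  pa <- as.matrix(co[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(la^2), `+`) - 2 * pa %*% t(la)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  sort(unique(co$res_index[mind <= cutoff]))
}

#' Theme enrichment of ligand-binding residues
#'
#' Compares, over all binding-annotated domains that carry at least one
#' theme interval, (i) the fraction of residues that lie in a theme
#' (`theme_residue_fraction` = theme residues / total residues) with
#' (ii) the fraction of binding residues that lie in a theme
#' (`binding_in_theme_fraction` = binding residues inside themes / all
#' binding residues). Under a uniform-random placement of binding residues
#' the two fractions agree in expectation; an excess of the second indicates
#' that themes are enriched for binding function. A residue bound by
#' several ligands counts once.
#'
#' @param domain_lengths Named integer vector of domain lengths, or a named
#'   list of [domain_record()]s.
#' @param themes data.frame with columns `domain_id`, `start`, `end`
#'   (1-based closed theme intervals; several per domain allowed).
#' @param annotations List of binding annotations (as from [read_biolip()]
#'   or built from [binding_residues()]), each with `domain_id` and
#'   `residues`.
#' @return Object of class `theme_enrichment`: the two aggregate fractions,
#'   totals, and a per-domain table of both ratios.
#' @export
theme_enrichment <- function(domain_lengths, themes, annotations) {
  if (is.list(domain_lengths) && !is.numeric(domain_lengths))
    domain_lengths <- vapply(domain_lengths,
                             function(r) nchar(r$sequence), integer(1))
  res_by_dom <- list()
  for (ann in annotations) {
    d <- ann$domain_id
    res_by_dom[[d]] <- sort(unique(c(res_by_dom[[d]], ann$residues)))
  }
  rows <- NULL
  for (d in names(res_by_dom)) {
    th <- themes[themes$domain_id == d, , drop = FALSE]
    if (nrow(th) == 0 || !(d %in% names(domain_lengths))) next
    len <- domain_lengths[[d]]
    theme_res <- sort(unique(unlist(
      Map(seq, th$start, th$end))))
    bind_res <- res_by_dom[[d]]
    bind_res <- bind_res[bind_res >= 1 & bind_res <= len]
    rows <- rbind(rows, data.frame(
      domain_id = d, length = len, n_theme = length(theme_res),
      n_binding = length(bind_res),
      n_binding_in_theme = sum(bind_res %in% theme_res),
      stringsAsFactors = FALSE))
  }
  if (is.null(rows))
    rows <- data.frame(domain_id = character(0), length = integer(0),
                       n_theme = integer(0), n_binding = integer(0),
                       n_binding_in_theme = integer(0))
  rows$theme_fraction <- ifelse(rows$length > 0,
                                rows$n_theme / rows$length, NA_real_)
  rows$binding_in_theme_fraction <-
    ifelse(rows$n_binding > 0,
           rows$n_binding_in_theme / rows$n_binding, NA_real_)
  structure(list(
    theme_residue_fraction =
      if (sum(rows$length)) sum(rows$n_theme) / sum(rows$length) else NA_real_,
    binding_in_theme_fraction =
      if (sum(rows$n_binding))
        sum(rows$n_binding_in_theme) / sum(rows$n_binding) else NA_real_,
    totals = list(residues = sum(rows$length),
                  theme_residues = sum(rows$n_theme),
                  binding_residues = sum(rows$n_binding),
                  binding_in_theme = sum(rows$n_binding_in_theme)),
    per_domain = rows), class = "theme_enrichment")
}

#' @export
print.theme_enrichment <- function(x, ...) {
  cat("<theme_enrichment> over", nrow(x$per_domain), "binding domain(s)\n")
  cat(sprintf("  theme residue fraction:      %.3f (%d / %d residues)\n",
              x$theme_residue_fraction, x$totals$theme_residues,
              x$totals$residues))
  cat(sprintf("  binding residues in themes:  %.3f (%d / %d binding)\n",
              x$binding_in_theme_fraction, x$totals$binding_in_theme,
              x$totals$binding_residues))
  invisible(x)
}
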