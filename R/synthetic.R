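#' Configuration for the synthetic planted-theme benchmark
#'
#' Defaults mirror the observed properties of curated bridging-theme sets:
#' themes of mean length ~49 residues hosted in domains of ~100 residues,
#' planted in two domains of different X-groups, with about half of the
#' planted domains carrying a ligand and 28% of planted pairs sharing the
#' same theme conformation (the similar-structure component of the observed
#' RMSD mixture).
#'
#' @param n_xgroups Number of distinct X-groups.
#' @param domains_per_group Domains generated per X-group.
#' @param n_themes Number of planted themes (each in 2 domains of different
#'   X-groups).
#' @param theme_length Planted theme length in residues.
#' @param theme_substitution_rate Per-site substitution probability applied
#'   independently to each variation of a theme ancestor.
#' @param flank_length_range Integer (min, max) for independently drawn
#'   flank lengths.
#' @param ligand_fraction Fraction of planted domains receiving a ligand.
#' @param same_conformation_fraction Probability that the two variations of
#'   a planted theme share the same backbone conformation.
#' @param multi_atom_ligands If `TRUE`, plant 4-atom tetrahedral iron-sulfur
#'   style clusters (edge 2.2 Angstrom) instead of single-atom ligands.
#' @param aa_frequencies Background amino-acid frequencies (named over the
#'   20-letter alphabet); default uniform.
#' @param seed Integer seed; the whole benchmark is a pure function of the
#'   configuration.
#' @return Object of class `plant_config`.
#' @export
plant_config <- function(n_xgroups = 20, domains_per_group = 5,
                         n_themes = 10, theme_length = 49,
                         theme_substitution_rate = 0.2,
                         flank_length_range = c(15, 40),
                         ligand_fraction = 0.5,
                         same_conformation_fraction = 0.28,
                         multi_atom_ligands = FALSE,
                         aa_frequencies = NULL, seed = 42) {
  stopifnot(n_xgroups >= 2, domains_per_group >= 1, n_themes >= 1,
            theme_length >= 20,
            theme_substitution_rate >= 0, theme_substitution_rate <= 1,
            length(flank_length_range) == 2,
            flank_length_range[1] >= 0,
            flank_length_range[2] >= flank_length_range[1],
            ligand_fraction >= 0, ligand_fraction <= 1,
            same_conformation_fraction >= 0,
            same_conformation_fraction <= 1)
  if (n_themes > floor(n_xgroups * domains_per_group / 2))
    stop("not enough domains to plant ", n_themes, " themes in disjoint ",
         "domain pairs")
  if (is.null(aa_frequencies))
    aa_frequencies <- setNames(rep(1 / 20, 20), AA20)
  structure(list(n_xgroups = n_xgroups,
                 domains_per_group = domains_per_group,
                 n_themes = n_themes, theme_length = theme_length,
                 theme_substitution_rate = theme_substitution_rate,
                 flank_length_range = as.integer(flank_length_range),
                 ligand_fraction = ligand_fraction,
                 same_conformation_fraction = same_conformation_fraction,
                 multi_atom_ligands = multi_atom_ligands,
                 aa_frequencies = aa_frequencies, seed = as.integer(seed)),
            class = "plant_config")
}

#' Draw an i.i.d. ancestor sequence from background frequencies
#'
#' @param length Sequence length (>= 1).
#' @param aa_frequencies Named frequencies over the 20 amino acids summing to
#'   1 (tolerance 1e-9); default uniform.
#' @param seed Optional seed.
#' @return Amino-acid string.
#' @export
sample_ancestor <- function(length, aa_frequencies = NULL, seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  if (is.null(aa_frequencies))
    aa_frequencies <- setNames(rep(1 / 20, 20), AA20)
  if (abs(sum(aa_frequencies) - 1) > 1e-9)
    stop("aa_frequencies must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(aa_frequencies), length, replace = TRUE,
               prob = aa_frequencies), collapse = "")
}

#' Evolve a variation of an ancestor by per-site substitution
#'
#' Each site is substituted independently with probability
#' `substitution_rate`; the replacement is drawn from the background
#' frequencies restricted to residues different from the current one.
#' Length is preserved (no indels).
#'
#' @param ancestor Amino-acid string.
#' @param substitution_rate Per-site substitution probability in \[0,1\].
#' @param aa_frequencies Background frequencies (default uniform).
#' @param seed Optional seed.
#' @return Amino-acid string of the same length.
#' @export
evolve_variation <- function(ancestor, substitution_rate,
                             aa_frequencies = NULL, seed = NULL) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1)
  if (is.null(aa_frequencies))
    aa_frequencies <- setNames(rep(1 / 20, 20), AA20)
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(ancestor, "")[[1]]
  hit <- runif(length(chars)) < substitution_rate
  for (i in which(hit)) {
    alt <- setdiff(names(aa_frequencies), chars[i])
    chars[i] <- sample(alt, 1, prob = aa_frequencies[alt])
  }
  paste(chars, collapse = "")
}

## --- toy backbone geometry ---------------------------------------------

## random unit vector
.runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

## random rotation matrix (QR of a Gaussian matrix, det fixed to +1)
.rrot <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

## C-alpha trace templates (n x 3), origin at first residue
.ca_template <- function(n, conformation) {
  i <- seq_len(n) - 1
  switch(conformation,
    helix = {
      # ideal alpha-helix: 1.5 A rise, 100 degree twist, 2.3 A radius
      th <- i * 100 * pi / 180
      cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
    },
    strand = {
      # extended zigzag: 3.3 A rise, alternating lateral offset so that
      # consecutive C-alpha atoms are 3.8 A apart
      cbind(3.3 * i, 0.942 * ((i %% 2) * 2 - 1), 0)
    },
    coil = {
      # random walk with 3.8 A steps
      steps <- t(vapply(seq_len(max(n - 1, 0)), function(k) 3.8 * .runit(),
                        numeric(3)))
      rbind(c(0, 0, 0), apply(steps, 2, cumsum))[seq_len(n), , drop = FALSE]
    },
    stop("unknown conformation: ", conformation))
}

## chain several segment templates: each segment is randomly rotated and
## translated so its first C-alpha sits 3.8 A from the previous last one
.chain_segments <- function(lengths, conformations) {
  keep <- lengths > 0
  lengths <- lengths[keep]; conformations <- conformations[keep]
  out <- NULL
  for (s in seq_along(lengths)) {
    seg <- .ca_template(lengths[s], conformations[s]) %*% .rrot()
    seg <- sweep(seg, 2, seg[1, ])
    origin <- if (is.null(out)) c(0, 0, 0) else out[nrow(out), ] + 3.8 * .runit()
    seg <- sweep(seg, 2, origin, `+`)
    out <- rbind(out, seg)
  }
  out
}

## pseudo C-beta positions: 1.53 A off the local backbone axis
.cb_from_ca <- function(ca) {
  n <- nrow(ca)
  cb <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    prev <- if (i > 1) ca[i - 1, ] else ca[i, ] - c(1, 0, 0)
    nxt <- if (i < n) ca[i + 1, ] else ca[i, ] + c(1, 0, 0)
    v <- ca[i, ] - (prev + nxt) / 2
    if (sqrt(sum(v^2)) < 1e-6) {
      axis <- nxt - prev
      v <- c(-axis[2], axis[1], 0)
      if (sqrt(sum(v^2)) < 1e-6) v <- c(1, 0, 0)
    }
    cb[i, ] <- ca[i, ] + 1.53 * v / sqrt(sum(v^2))
  }
  cb
}

#' Build a synthetic domain around a theme variation
#'
#' The domain sequence is `flank_before + theme_seq + flank_after`. C-alpha
#' and C-beta coordinates are laid on ideal-geometry templates: the theme
#' adopts the requested conformation (helix: 1.5 Angstrom rise / 100 degree
#' twist; strand: 3.3 Angstrom rise with alternating lateral offset; coil:
#' 3.8 Angstrom random walk) and the flanks are coil. Consecutive C-alpha
#' distances are within \[3.7, 3.9\] Angstrom throughout. If a ligand is
#' requested, it is placed 3.0 Angstrom from the C-beta (C-alpha for
#' glycine) of a designated theme residue.
#'
#' @param theme_seq Theme variation sequence.
#' @param flank_before,flank_after Flank sequences (may be empty strings).
#' @param domain_id Identifier for the new domain.
#' @param classification A.X.H.T.F label for the new domain.
#' @param conformation `"helix"`, `"strand"` or `"coil"` for the theme.
#' @param ligand `FALSE` (default), or `TRUE` to plant a single-atom zinc
#'   ligand, or a component code string.
#' @param ligand_site 1-based index *within the theme* of the residue the
#'   ligand is anchored to (default: middle of the theme).
#' @param multi_atom If `TRUE`, plant a 4-atom tetrahedral cluster (edge 2.2
#'   Angstrom) instead of a single atom.
#' @param seed Optional seed.
#' @return List with `record` ([domain_record()]), `ligand`
#'   ([ligand_instance()] or `NULL`), `ligand_site` (domain-level residue
#'   index or `NA`) and `theme_interval` (1-based closed `c(start, end)`).
#' @export
build_domain <- function(theme_seq, flank_before = "", flank_after = "",
                         domain_id = "synth1", classification = "1.1.1.1.1",
                         conformation = c("helix", "strand", "coil"),
                         ligand = FALSE, ligand_site = NULL,
                         multi_atom = FALSE, seed = NULL) {
  conformation <- match.arg(conformation)
  if (!is.null(seed)) set.seed(seed)
  if (nchar(theme_seq) < 1) stop("theme_seq must be non-empty")
  sequence <- paste0(flank_before, theme_seq, flank_after)
  nb <- nchar(flank_before); nt <- nchar(theme_seq); na_ <- nchar(flank_after)
  n <- nb + nt + na_
  if (nt > n) stop("theme longer than domain")
  ca <- .chain_segments(c(nb, nt, na_), c("coil", conformation, "coil"))
  cb <- .cb_from_ca(ca)
  chars <- strsplit(sequence, "")[[1]]
  has_cb <- chars != "G"
  coords <- rbind(
    data.frame(res_index = seq_len(n), resname = bio3d::aa123(chars),
               atom = "CA", x = ca[, 1], y = ca[, 2], z = ca[, 3],
               author_resno = seq_len(n), stringsAsFactors = FALSE),
    data.frame(res_index = which(has_cb),
               resname = bio3d::aa123(chars[has_cb]),
               atom = "CB", x = cb[has_cb, 1], y = cb[has_cb, 2],
               z = cb[has_cb, 3], author_resno = which(has_cb),
               stringsAsFactors = FALSE))
  coords <- coords[order(coords$res_index, coords$atom), ]
  rownames(coords) <- NULL
  ss_theme <- switch(conformation, helix = "H", strand = "E", coil = "C")
  ss <- paste0(strrep("C", nb), strrep(ss_theme, nt), strrep("C", na_))
  rec <- domain_record(domain_id, sequence, classification,
                       coords = coords, ss = ss)
  lig <- NULL; site <- NA_integer_
  if (!identical(ligand, FALSE)) {
    code <- if (isTRUE(ligand)) if (multi_atom) "SF4" else "ZN" else ligand
    if (is.null(ligand_site)) ligand_site <- ceiling(nt / 2)
    stopifnot(ligand_site >= 1, ligand_site <= nt)
    site <- nb + ligand_site
    anchor <- if (has_cb[site]) cb[site, ] else ca[site, ]
    center <- anchor + 3.0 * .runit()
    if (multi_atom) {
      # regular tetrahedron, edge 2.2 A -> circumradius 2.2*sqrt(3/8)
      r <- 2.2 * sqrt(3 / 8)
      verts <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
      verts <- verts / sqrt(3) * r
      pos <- sweep(verts %*% .rrot(), 2, center, `+`)
      atoms <- data.frame(element = c("FE", "S", "FE", "S"),
                          x = pos[, 1], y = pos[, 2], z = pos[, 3])
    } else {
      atoms <- data.frame(element = "ZN", x = center[1], y = center[2],
                          z = center[3])
    }
    lig <- ligand_instance(code, atoms, domain_id)
  }
  list(record = rec, ligand = lig, ligand_site = site,
       theme_interval = c(nb + 1L, nb + nt))
}

## write one synthetic domain (CA/CB + optional ligand HETATM) as PDB
.write_domain_pdb <- function(rec, ligand, path) {
  co <- rec$coords
  xyz <- as.numeric(t(as.matrix(co[, c("x", "y", "z")])))
  resno <- co$author_resno; resid <- co$resname; elety <- co$atom
  type <- rep("ATOM", nrow(co))
  if (!is.null(ligand)) {
    la <- ligand$atoms
    xyz <- c(xyz, as.numeric(t(as.matrix(la[, c("x", "y", "z")]))))
    resno <- c(resno, rep(max(co$author_resno) + 1L, nrow(la)))
    resid <- c(resid, rep(ligand$ligand_code, nrow(la)))
    elety <- c(elety, la$element)
    type <- c(type, rep("HETATM", nrow(la)))
  }
  bio3d::write.pdb(file = path, xyz = xyz, type = type, resno = resno,
                   resid = resid, elety = elety,
                   chain = rep("A", length(resno)))
  invisible(path)
}

#' Generate the synthetic planted-theme benchmark
#'
#' Writes a complete synthetic input set for the pipeline: domain sequences
#' (FASTA), per-domain PDB files with toy coordinates (and planted ligands),
#' a classification TSV, a theme-hit TSV (planted occurrences at E-value
#' 1e-6 / coverage 1.0 plus one decoy hit per theme at E-value 1e-2), a
#' BioLiP-style binding TSV (computed geometrically from the planted
#' ligands, so the distance- and annotation-based routes agree by
#' construction), a per-domain secondary-structure TSV and a ground-truth
#' TSV. Each planted theme occurs in exactly two domains with different
#' X-group labels; every other domain is pure background.
#'
#' @param config A [plant_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `records`
#'   (list of [domain_record()]), `ligands`, `truth` and `hits` data frames
#'   (1-based closed intervals).
#' @export
generate_benchmark <- function(config, out_dir) {
  stopifnot(inherits(config, "plant_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("output directory not writable: ", out_dir)
  pdb_dir <- file.path(out_dir, "pdb")
  dir.create(pdb_dir, showWarnings = FALSE)
  set.seed(config$seed)

  ng <- config$n_xgroups; nd <- config$domains_per_group
  xgroup_ids <- 100 + seq_len(ng)
  aclass <- ((seq_len(ng) - 1) %% 6) + 1  # cycle the six structural classes
  dom_meta <- data.frame(
    domain_id = sprintf("d%04d", seq_len(ng * nd)),
    xgroup = rep(xgroup_ids, each = nd),
    classification = rep(sprintf("%d.%d.1.1.1", aclass, xgroup_ids),
                         each = nd),
    stringsAsFactors = FALSE)

  # assign disjoint domain pairs (different X-groups) to the planted themes
  theme_ids <- sprintf("t%03d", seq_len(config$n_themes))
  avail <- split(dom_meta$domain_id, dom_meta$xgroup)
  plant <- list()
  groups_order <- sample(names(avail))
  gi <- 1
  for (t in theme_ids) {
    # take the next two groups that still have unplanted domains
    gs <- character(0)
    while (length(gs) < 2) {
      g <- groups_order[((gi - 1) %% length(groups_order)) + 1]
      gi <- gi + 1
      if (length(avail[[g]]) > 0 && !(g %in% gs)) gs <- c(gs, g)
    }
    d1 <- avail[[gs[1]]][1]; avail[[gs[1]]] <- avail[[gs[1]]][-1]
    d2 <- avail[[gs[2]]][1]; avail[[gs[2]]] <- avail[[gs[2]]][-1]
    plant[[t]] <- c(d1, d2)
  }

  flank_len <- function() sample(seq(config$flank_length_range[1],
                                     config$flank_length_range[2]), 1)
  records <- list(); ligands <- list()
  truth <- NULL; hits <- NULL; biolip <- NULL
  planted_domains <- unlist(plant)

  for (t in theme_ids) {
    ancestor <- sample_ancestor(config$theme_length, config$aa_frequencies)
    doms <- plant[[t]]
    conf1 <- "helix"
    conf2 <- if (runif(1) < config$same_conformation_fraction) "helix"
             else "strand"
    confs <- c(conf1, conf2)
    site <- sample(seq(5, config$theme_length - 5), 1)
    for (k in 1:2) {
      did <- doms[k]
      meta <- dom_meta[dom_meta$domain_id == did, ]
      variation <- evolve_variation(ancestor, config$theme_substitution_rate,
                                    config$aa_frequencies)
      fb <- sample_ancestor(flank_len(), config$aa_frequencies)
      fa <- sample_ancestor(flank_len(), config$aa_frequencies)
      want_lig <- runif(1) < config$ligand_fraction
      built <- build_domain(variation, fb, fa, domain_id = did,
                            classification = meta$classification,
                            conformation = confs[k], ligand = want_lig,
                            ligand_site = site,
                            multi_atom = config$multi_atom_ligands)
      records[[did]] <- built$record
      iv <- built$theme_interval
      truth <- rbind(truth, data.frame(
        theme_id = t, domain_id = did, start = iv[1], end = iv[2],
        partner = doms[doms != did], conformation = confs[k],
        planted = TRUE, stringsAsFactors = FALSE))
      hits <- rbind(hits, data.frame(
        theme_id = t, domain_id = did, start = iv[1], end = iv[2],
        e_value = 1e-6, coverage = 1.0, stringsAsFactors = FALSE))
      if (want_lig) {
        ligands[[did]] <- built$ligand
        bres <- binding_residues(built$record$coords, built$ligand)
        biolip <- rbind(biolip, data.frame(
          domain_id = did, ligand_code = built$ligand$ligand_code,
          residues = paste(bres, collapse = " "), stringsAsFactors = FALSE))
      }
    }
  }

  # background domains: random sequence, coil backbone
  for (did in setdiff(dom_meta$domain_id, planted_domains)) {
    meta <- dom_meta[dom_meta$domain_id == did, ]
    len <- config$theme_length + flank_len() + flank_len()
    seqs <- sample_ancestor(len, config$aa_frequencies)
    built <- build_domain(seqs, "", "", domain_id = did,
                          classification = meta$classification,
                          conformation = "coil")
    records[[did]] <- built$record
  }

  # decoy hits: one per theme, random background domain, E-value above the
  # downstream threshold so none can survive filtering
  bg <- setdiff(dom_meta$domain_id, planted_domains)
  for (t in theme_ids) {
    did <- if (length(bg) > 0) sample(bg, 1) else sample(planted_domains, 1)
    len <- nchar(records[[did]]$sequence)
    st <- sample(seq_len(max(len - 25, 1)), 1)
    hits <- rbind(hits, data.frame(
      theme_id = t, domain_id = did, start = st,
      end = min(st + 24, len), e_value = 1e-2, coverage = 0.9,
      stringsAsFactors = FALSE))
  }
  rownames(hits) <- NULL

  records <- records[dom_meta$domain_id]
  paths <- list(
    fasta = file.path(out_dir, "domains.fasta"),
    pdb_dir = pdb_dir,
    classification = file.path(out_dir, "classification.tsv"),
    hits = file.path(out_dir, "hits.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    ss = file.path(out_dir, "ss.tsv"),
    biolip = file.path(out_dir, "biolip.tsv"))
  write_fasta(vapply(records, `[[`, character(1), "sequence"), paths$fasta)
  write_classification(setNames(dom_meta$classification, dom_meta$domain_id),
                       paths$classification)
  write_hits(hits, paths$hits)
  truth_out <- truth
  truth_out$start <- truth_out$start - 1L  # 0-based half-open on disk
  write.table(truth_out, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ss <- vapply(records, `[[`, character(1), "ss")
  write.table(data.frame(names(ss), unname(ss)), paths$ss, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(biolip))
    write.table(biolip, paths$biolip, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  for (did in names(records))
    .write_domain_pdb(records[[did]], ligands[[did]],
                      file.path(pdb_dir, paste0(did, ".pdb")))
  invisible(list(paths = paths, records = records, ligands = ligands,
                 truth = truth, hits = hits))
}
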