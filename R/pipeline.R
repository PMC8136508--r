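#' Pipeline run configuration
#'
#' Collects input paths, all numeric thresholds (with the standard defaults
#' used throughout the pipeline: E-value 1e-3, coverage 0.85, flank rules
#' 20 residues / 25 percent identity, RMSD similarity threshold 6 Angstrom,
#' contact thresholds 9 and 11 Angstrom, ligand distance cutoff 4.5
#' Angstrom), the alignment parameters and the seed.
#'
#' @param fasta,pdb_dir,classification,hits Input paths (required by
#'   [run_all()]).
#' @param biolip,ss,tm Optional input paths: BioLiP-style binding TSV,
#'   per-domain secondary-structure TSV, TM-score TSV (domain_a, domain_b,
#'   tm_score; passed through to reports, never computed).
#' @param e_max,cov_min Hit-filter thresholds.
#' @param flank_min_len,flank_max_id Flank-filter thresholds.
#' @param sw_min_len Local-alignment length below which the global fallback
#'   is used.
#' @param rmsd_threshold Similar/dissimilar RMSD threshold (Angstrom).
#' @param contact_thresholds Two contact-map thresholds (Angstrom).
#' @param binding_cutoff Ligand distance cutoff (Angstrom).
#' @param gap_open,gap_extend Affine gap parameters.
#' @param matrix_file Optional NCBI-format substitution matrix path
#'   (default: shipped BLOSUM62).
#' @param pvalue_samples Null-sample size per candidate P-value.
#' @param seed Integer seed governing every random draw of a run.
#' @return Object of class `run_config`.
#' @export
run_config <- function(fasta = NULL, pdb_dir = NULL, classification = NULL,
                       hits = NULL, biolip = NULL, ss = NULL, tm = NULL,
                       e_max = 1e-3, cov_min = 0.85,
                       flank_min_len = 20, flank_max_id = 25,
                       sw_min_len = 20, rmsd_threshold = 6.0,
                       contact_thresholds = c(9, 11),
                       binding_cutoff = 4.5, gap_open = 11, gap_extend = 1,
                       matrix_file = NULL, pvalue_samples = 1000,
                       seed = 1) {
  stopifnot(e_max > 0, cov_min >= 0, cov_min <= 1, flank_min_len > 0,
            flank_max_id > 0, sw_min_len > 0, rmsd_threshold > 0,
            all(contact_thresholds > 0), binding_cutoff > 0,
            gap_open >= 0, gap_extend >= 0, pvalue_samples >= 0)
  structure(list(fasta = fasta, pdb_dir = pdb_dir,
                 classification = classification, hits = hits,
                 biolip = biolip, ss = ss, tm = tm,
                 e_max = e_max, cov_min = cov_min,
                 flank_min_len = flank_min_len, flank_max_id = flank_max_id,
                 sw_min_len = sw_min_len, rmsd_threshold = rmsd_threshold,
                 contact_thresholds = contact_thresholds,
                 binding_cutoff = binding_cutoff,
                 gap_open = gap_open, gap_extend = gap_extend,
                 matrix_file = matrix_file,
                 pvalue_samples = pvalue_samples,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; missing keys take the
#' defaults. Relative input paths are resolved against the file's
#' directory.
#'
#' @param path Path to a YAML configuration.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  base <- dirname(normalizePath(path))
  for (k in c("fasta", "pdb_dir", "classification", "hits", "biolip", "ss",
              "tm", "matrix_file"))
    if (!is.null(vals[[k]]) && !grepl("^/", vals[[k]]))
      vals[[k]] <- file.path(base, vals[[k]])
  do.call(run_config, vals)
}

.require_path <- function(path, what) {
  if (is.null(path)) stop("config is missing the ", what, " path")
  if (!file.exists(path)) stop(what, " not found: ", path)
  path
}

#' Run the full bridging-theme pipeline
#'
#' Orchestrates detection, structural comparison, binding analysis and
#' network construction from one configuration, writing every stage output
#' under `out_dir` plus a machine-readable JSON run report. The run is a
#' pure function of (inputs, config, seed): re-running with the same
#' configuration reproduces the outputs exactly.
#'
#' Outputs: `bridges.tsv`, `structure_metrics.tsv`, `rmsd_mixture.json`
#' (when at least 10 finite RMSDs are available), `enrichment.tsv`,
#' `overview.graphml`, `overview.sif` (+ attribute sidecar), `report.json`.
#'
#' @param config A [run_config()] or path to a YAML configuration.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the run report as a list.
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  matrix <- if (is.null(config$matrix_file)) blosum62()
            else read_score_matrix(config$matrix_file)

  ## --- inputs ----------------------------------------------------------
  seqs <- read_fasta(.require_path(config$fasta, "FASTA"))
  classification <- read_classification(
    .require_path(config$classification, "classification table"))
  hits <- read_hits(.require_path(config$hits, "hit table"))
  pdb_dir <- .require_path(config$pdb_dir, "PDB directory")
  ss <- if (!is.null(config$ss)) read_ss(config$ss) else NULL

  ## --- stage: detect ---------------------------------------------------
  message("detect: ", nrow(hits), " hit(s), ", length(seqs), " domain(s)")
  bridges <- tryCatch(
    detect_bridges(seqs, hits, classification,
                   e_max = config$e_max, cov_min = config$cov_min,
                   matrix = matrix, gap_open = config$gap_open,
                   gap_extend = config$gap_extend,
                   sw_min_len = config$sw_min_len,
                   flank_min_len = config$flank_min_len,
                   flank_max_id = config$flank_max_id,
                   pvalue_samples = config$pvalue_samples,
                   seed = config$seed),
    error = function(e) stop("stage 'detect' failed: ", conditionMessage(e)))
  write_bridges(bridges, file.path(out_dir, "bridges.tsv"))

  ## --- stage: structure ------------------------------------------------
  need <- sort(unique(c(bridges$table$domain_a, bridges$table$domain_b)))
  records <- list()
  for (d in need) {
    pdb <- file.path(pdb_dir, paste0(d, ".pdb"))
    if (!file.exists(pdb)) next
    st <- tryCatch(read_structure(pdb),
                   error = function(e) stop("stage 'structure' failed on ",
                                            d, ": ", conditionMessage(e)))
    records[[d]] <- domain_record(
      d, seqs[[d]] %||% st$sequence, classification[[d]] %||% "NA.NA",
      coords = st$coords,
      ss = if (!is.null(ss) && d %in% names(ss)) ss[[d]] else NULL)
    attr(records[[d]], "ligands") <- st$ligands
  }
  metrics <- compute_structure_metrics(
    bridges, records, contact_thresholds = config$contact_thresholds,
    rmsd_threshold = config$rmsd_threshold)
  if (!is.null(config$tm) && file.exists(config$tm)) {
    tmtab <- read.table(config$tm, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    metrics$tm_score <- tmtab$tm_score[match(
      key(metrics$domain_a, metrics$domain_b),
      key(tmtab$domain_a, tmtab$domain_b))]
  }
  write.table(metrics, file.path(out_dir, "structure_metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rmsds <- metrics$rmsd_ca[is.finite(metrics$rmsd_ca)]
  mixture <- NULL
  if (length(rmsds) >= 10 && sd(rmsds) > 0) {
    mixture <- fit_rmsd_mixture(rmsds, seed = config$seed)
    jsonlite::write_json(
      list(weights = mixture$weights, means = mixture$means,
           sds = mixture$sds, loglik = mixture$loglik,
           n_iter = mixture$n_iter, converged = mixture$converged,
           n = mixture$n),
      file.path(out_dir, "rmsd_mixture.json"), auto_unbox = TRUE,
      digits = NA)
  }

  ## --- stage: binding --------------------------------------------------
  themes <- data.frame(domain_id = c(bridges$table$domain_a,
                                     bridges$table$domain_b),
                       start = c(bridges$table$start_a,
                                 bridges$table$start_b),
                       end = c(bridges$table$end_a, bridges$table$end_b),
                       stringsAsFactors = FALSE)
  annotations <- list()
  for (d in names(records)) {
    ligs <- filter_ligands(attr(records[[d]], "ligands") %||% list())
    for (l in ligs) {
      res <- binding_residues(records[[d]]$coords, l,
                              cutoff = config$binding_cutoff)
      if (length(res))
        annotations[[length(annotations) + 1L]] <-
          list(domain_id = d, ligand_code = l$ligand_code,
               residues = res, method = "distance")
    }
  }
  if (!is.null(config$biolip) && file.exists(config$biolip))
    annotations <- c(annotations, read_biolip(config$biolip))
  enrichment <- theme_enrichment(records, themes, annotations)
  write.table(enrichment$per_domain, file.path(out_dir, "enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- stage: network --------------------------------------------------
  network_counts <- list(nodes = 0L, edges = 0L)
  if (nrow(bridges$table) > 0) {
    overview <- build_overview(bridges$table, classification)
    export_graph(overview, file.path(out_dir, "overview.graphml"), "graphml")
    export_graph(overview, file.path(out_dir, "overview.sif"), "sif")
    network_counts <- list(nodes = igraph::vcount(overview$graph),
                           edges = igraph::ecount(overview$graph))
  }

  ## --- report ----------------------------------------------------------
  report <- list(
    package_version = as.character(packageVersion("bridgethemes")),
    seed = config$seed,
    config = unclass(config),
    counts = list(
      hits_in = bridges$stats$hits_in,
      hits_kept = bridges$stats$hits_kept,
      candidate_groups = bridges$stats$groups,
      candidates = bridges$stats$candidates,
      representatives = bridges$stats$representatives,
      structural_similar = sum(metrics$class == "similar", na.rm = TRUE),
      structural_dissimilar = sum(metrics$class == "dissimilar",
                                  na.rm = TRUE),
      binding_domains = nrow(enrichment$per_domain),
      network_nodes = network_counts$nodes,
      network_edges = network_counts$edges),
    enrichment = list(
      theme_residue_fraction = enrichment$theme_residue_fraction,
      binding_in_theme_fraction = enrichment$binding_in_theme_fraction),
    mixture = if (!is.null(mixture))
      list(weights = mixture$weights, means = mixture$means,
           sds = mixture$sds))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
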