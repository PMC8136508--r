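#' Filter theme hits by E-value and coverage
#'
#' Keeps hits with `e_value <= e_max` and `coverage >= cov_min`.
#'
#' @param hits Hit data.frame (as from [read_hits()]).
#' @param e_max E-value threshold (default 1e-3).
#' @param cov_min Minimum coverage (default 0.85).
#' @return Filtered data.frame (possibly empty), order preserved.
#' @export
filter_hits <- function(hits, e_max = 1e-3, cov_min = 0.85) {
  hits[hits$e_value <= e_max & hits$coverage >= cov_min, , drop = FALSE]
}

#' Group filtered hits into cross-X-group candidate sets
#'
#' For each theme, hit domains are partitioned by X-group (second field of
#' the classification label); one candidate group is formed per unordered
#' X-group pair with hits on both sides. Hits on unclassified domains are
#' dropped with a warning; within-X-group pairs are discarded. A domain
#' hit several times by the same theme contributes its lowest-E-value hit.
#'
#' @param hits Filtered hit data.frame.
#' @param classification Named label vector (from [read_classification()]).
#' @return List of candidate groups, each a list with `theme_id`, `xgroups`
#'   (sorted pair), `hits_a`, `hits_b` (hit rows per side), `n1`, `n2`.
#'   Deterministically ordered by (theme_id, X-group pair).
#' @export
cross_group_pairs <- function(hits, classification) {
  known <- hits$domain_id %in% names(classification)
  if (any(!known)) {
    warning(sum(!known), " hit(s) on unclassified domains dropped: ",
            paste(unique(hits$domain_id[!known]), collapse = ", "))
    hits <- hits[known, , drop = FALSE]
  }
  if (nrow(hits) == 0) return(list())
  # per (theme, domain): keep the lowest-E-value hit
  hits <- hits[order(hits$theme_id, hits$domain_id, hits$e_value), ]
  hits <- hits[!duplicated(hits[c("theme_id", "domain_id")]), , drop = FALSE]
  hits$xgroup <- xgroup_of(classification[hits$domain_id])
  groups <- list()
  for (t in sort(unique(hits$theme_id))) {
    th <- hits[hits$theme_id == t, , drop = FALSE]
    xgs <- sort(unique(th$xgroup))
    if (length(xgs) < 2) next
    for (a in seq_along(xgs)[-length(xgs)]) for (b in seq((a + 1), length(xgs))) {
      ha <- th[th$xgroup == xgs[a], , drop = FALSE]
      hb <- th[th$xgroup == xgs[b], , drop = FALSE]
      ha <- ha[order(ha$domain_id), , drop = FALSE]
      hb <- hb[order(hb$domain_id), , drop = FALSE]
      groups[[length(groups) + 1L]] <- list(
        theme_id = t, xgroups = c(xgs[a], xgs[b]),
        hits_a = ha, hits_b = hb,
        n1 = nrow(ha), n2 = nrow(hb))
    }
  }
  groups
}

#' Split a domain sequence around a theme hit
#'
#' @param sequence Domain sequence.
#' @param start,end 1-based closed theme interval.
#' @return List with `before`, `theme`, `after` (concatenation equals the
#'   input; flanks may be empty strings).
#' @export
split_context <- function(sequence, start, end) {
  n <- nchar(sequence)
  if (start < 1 || end > n || start > end)
    stop("theme interval [", start, ", ", end, "] out of range for a ",
         n, "-residue sequence")
  list(before = substr(sequence, 1, start - 1),
       theme = substr(sequence, start, end),
       after = substr(sequence, end + 1, n))
}

#' Align one cross-X-group domain pair into a bridge candidate
#'
#' The theme segments are aligned with local Smith-Waterman; if the local
#' alignment covers 20 or fewer residues the global Needleman-Wunsch
#' alignment of the theme segments is used instead (the local aligner may
#' trim a genuinely homologous segment below the length threshold). The
#' flanking segments before and after the theme are always aligned with
#' Smith-Waterman. A flank "passes" (i.e. the context is judged different)
#' iff its best local alignment is shorter than `flank_min_len` residues or
#' has percent identity below `flank_max_id`. The significance of the chosen
#' theme alignment is assessed with [alignment_pvalue()].
#'
#' @param record_a,record_b [domain_record()]s of the two domains.
#' @param hit_a,hit_b One-row hit data frames for the same theme on each
#'   domain.
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @param sw_min_len Local alignments of at most this many residues trigger
#'   the global fallback (default 20).
#' @param flank_min_len,flank_max_id Flank-filter thresholds (default 20
#'   residues / 25 percent identity).
#' @param pvalue_samples Null-sample size for the P-value (default 1000);
#'   set to 0 to skip.
#' @param seed Optional seed for the P-value null sample.
#' @return Object of class `bridge_candidate`.
#' @export
align_candidate <- function(record_a, record_b, hit_a, hit_b,
                            matrix = blosum62(), gap_open = 11,
                            gap_extend = 1, sw_min_len = 20,
                            flank_min_len = 20, flank_max_id = 25,
                            pvalue_samples = 1000, seed = NULL) {
  ctx_a <- split_context(record_a$sequence, hit_a$start, hit_a$end)
  ctx_b <- split_context(record_b$sequence, hit_b$start, hit_b$end)
  if (nchar(ctx_a$theme) == 0 || nchar(ctx_b$theme) == 0)
    stop("empty theme segment")
  theme_aln <- smith_waterman(ctx_a$theme, ctx_b$theme, matrix,
                              gap_open, gap_extend)
  if (theme_aln$n_aligned <= sw_min_len)
    theme_aln <- needleman_wunsch(ctx_a$theme, ctx_b$theme, matrix,
                                  gap_open, gap_extend)
  sw_flank <- function(a, b) {
    if (nchar(a) == 0 || nchar(b) == 0)
      .empty_alignment("local", gap_open, gap_extend)
    else smith_waterman(a, b, matrix, gap_open, gap_extend)
  }
  before_aln <- sw_flank(ctx_a$before, ctx_b$before)
  after_aln <- sw_flank(ctx_a$after, ctx_b$after)
  fp <- flank_filter(before_aln, after_aln, flank_min_len, flank_max_id)
  p <- if (pvalue_samples > 0)
    alignment_pvalue(ctx_a$theme, ctx_b$theme, theme_aln$score,
                     mode = theme_aln$mode, matrix = matrix,
                     gap_open = gap_open, gap_extend = gap_extend,
                     n_samples = pvalue_samples, seed = seed)$p_value
  else NA_real_
  structure(list(theme_id = hit_a$theme_id,
                 domain_a = record_a$domain_id,
                 domain_b = record_b$domain_id,
                 xgroup_a = xgroup_of(record_a$classification),
                 xgroup_b = xgroup_of(record_b$classification),
                 hit_a = hit_a, hit_b = hit_b,
                 theme_aln = theme_aln,
                 before_aln = before_aln, after_aln = after_aln,
                 flank_pass_before = fp[["before"]],
                 flank_pass_after = fp[["after"]],
                 p_value = p),
            class = "bridge_candidate")
}

#' @export
print.bridge_candidate <- function(x, ...) {
  cat("<bridge_candidate> theme ", x$theme_id, ": ", x$domain_a, " (X=",
      x$xgroup_a, ") vs ", x$domain_b, " (X=", x$xgroup_b, ")\n", sep = "")
  cat("  theme: ", x$theme_aln$mode, ", score ", x$theme_aln$score,
      ", ", x$theme_aln$n_aligned, " residues",
      if (is.finite(x$p_value)) sprintf(", p=%.3g", x$p_value), "\n",
      sep = "")
  invisible(x)
}

#' Flank context filter
#'
#' A flank passes (context judged non-homologous) iff its best local
#' alignment is too short (`n_aligned < min_len`) or too dissimilar
#' (`pct_identity < max_id`). Failing candidates are retained downstream but
#' flagged.
#'
#' @param before_aln,after_aln Local [smith_waterman()] results of the two
#'   flank pairs.
#' @param min_len Length rule threshold (default 20 residues).
#' @param max_id Identity rule threshold (default 25 percent).
#' @return Named logical vector `c(before =, after =)`.
#' @export
flank_filter <- function(before_aln, after_aln, min_len = 20, max_id = 25) {
  pass1 <- function(a) {
    a$n_aligned < min_len ||
      (is.finite(a$pct_identity) && a$pct_identity < max_id)
  }
  c(before = pass1(before_aln), after = pass1(after_aln))
}

## mean flank score of a candidate (absent flank alignment contributes 0)
.flank_score <- function(cand) {
  (cand$before_aln$score + cand$after_aln$score) / 2
}

#' Select representative candidates from a candidate group
#'
#' If the group holds a single candidate it is returned as is. Otherwise
#' theme-alignment scores and mean flank scores are z-normalised across the
#' group (zero standard deviation yields all-zero z-scores) and the two
#' candidates maximising `z_theme - z_flank` -- the strongest theme
#' similarity against the weakest context similarity -- are returned.
#' Ties break by lower theme E-value, then lexicographic domain-id pair.
#'
#' @param candidates List of [align_candidate()] results for one
#'   theme / X-group pair.
#' @return List of 1 or 2 `bridge_candidate`s (a subset of the input).
#' @export
select_representatives <- function(candidates) {
  stopifnot(length(candidates) >= 1)
  if (length(candidates) == 1) return(candidates)
  zed <- function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  theme_scores <- vapply(candidates, function(c) c$theme_aln$score, 1)
  flank_scores <- vapply(candidates, .flank_score, 1)
  diff <- zed(theme_scores) - zed(flank_scores)
  evals <- vapply(candidates, function(c) min(c$hit_a$e_value,
                                              c$hit_b$e_value), 1)
  pair_id <- vapply(candidates,
                    function(c) paste(c$domain_a, c$domain_b), "")
  ord <- order(-diff, evals, pair_id)
  candidates[ord[1:2]]
}

#' Keep only the longest theme per domain pair
#'
#' When a domain pair is connected through several themes, only the
#' candidate whose theme alignment covers the most residues is kept
#' (ties: higher theme score, then lexicographically smallest theme id).
#'
#' @param candidates List of `bridge_candidate`s.
#' @return Deduplicated list, in input order of the survivors.
#' @export
dedupe_longest <- function(candidates) {
  if (length(candidates) <= 1) return(candidates)
  key <- vapply(candidates, function(c)
    paste(sort(c(c$domain_a, c$domain_b)), collapse = "|"), "")
  nal <- vapply(candidates, function(c) c$theme_aln$n_aligned, 1)
  sc <- vapply(candidates, function(c) c$theme_aln$score, 1)
  tid <- vapply(candidates, function(c) c$theme_id, "")
  keep <- logical(length(candidates))
  for (k in unique(key)) {
    idx <- which(key == k)
    best <- idx[order(-nal[idx], -sc[idx], tid[idx])][1]
    keep[best] <- TRUE
  }
  candidates[keep]
}

## flatten candidates to the bridge table
.candidate_row <- function(c) {
  data.frame(
    theme_id = c$theme_id, domain_a = c$domain_a, domain_b = c$domain_b,
    xgroup_a = c$xgroup_a, xgroup_b = c$xgroup_b,
    start_a = c$hit_a$start, end_a = c$hit_a$end,
    start_b = c$hit_b$start, end_b = c$hit_b$end,
    mode = c$theme_aln$mode, score = c$theme_aln$score,
    n_aligned = c$theme_aln$n_aligned,
    pct_identity = c$theme_aln$pct_identity,
    pct_similarity = c$theme_aln$pct_similarity,
    p_value = c$p_value,
    before_n = c$before_aln$n_aligned, before_id = c$before_aln$pct_identity,
    before_score = c$before_aln$score,
    after_n = c$after_aln$n_aligned, after_id = c$after_aln$pct_identity,
    after_score = c$after_aln$score,
    flank_pass_before = c$flank_pass_before,
    flank_pass_after = c$flank_pass_after,
    stringsAsFactors = FALSE)
}

#' Detect bridging themes from hits, sequences and a classification
#'
#' Runs the full detection stage: E-value/coverage filtering, cross-X-group
#' pairing, per-pair alignment (local with global fallback), flank
#' filtering, representative selection within each theme / X-group pair
#' group, and per-domain-pair deduplication keeping the longest theme.
#' The result is a pure function of its inputs and `seed`.
#'
#' @param sequences Named character vector of domain sequences, or a list of
#'   [domain_record()]s.
#' @param hits Hit data.frame (from [read_hits()]).
#' @param classification Named label vector.
#' @param e_max,cov_min Hit-filter thresholds.
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @param sw_min_len,flank_min_len,flank_max_id See [align_candidate()].
#' @param pvalue_samples Null-sample size per candidate P-value (0 skips).
#' @param seed Integer seed for the P-value null samples.
#' @return Object of class `bridge_set`: list with `table` (one row per
#'   representative candidate), `candidates` (the representative
#'   `bridge_candidate` objects) and `stats` (counts per stage).
#' @export
detect_bridges <- function(sequences, hits, classification,
                           e_max = 1e-3, cov_min = 0.85,
                           matrix = blosum62(), gap_open = 11,
                           gap_extend = 1, sw_min_len = 20,
                           flank_min_len = 20, flank_max_id = 25,
                           pvalue_samples = 1000, seed = 1) {
  if (is.list(sequences)) {
    records <- sequences
  } else {
    records <- lapply(names(sequences), function(id)
      domain_record(id, sequences[[id]],
                    classification[[id]] %||% "NA.NA"))
    names(records) <- names(sequences)
  }
  n_in <- nrow(hits)
  hits <- filter_hits(hits, e_max, cov_min)
  known_dom <- hits$domain_id %in% names(records)
  if (any(!known_dom)) {
    warning(sum(!known_dom), " hit(s) on domains without sequences dropped")
    hits <- hits[known_dom, , drop = FALSE]
  }
  groups <- cross_group_pairs(hits, classification)
  reps <- list()
  cand_counter <- 0L
  for (g in groups) {
    cands <- list()
    for (ia in seq_len(g$n1)) for (ib in seq_len(g$n2)) {
      cand_counter <- cand_counter + 1L
      cands[[length(cands) + 1L]] <- align_candidate(
        records[[g$hits_a$domain_id[ia]]], records[[g$hits_b$domain_id[ib]]],
        g$hits_a[ia, ], g$hits_b[ib, ],
        matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
        sw_min_len = sw_min_len, flank_min_len = flank_min_len,
        flank_max_id = flank_max_id, pvalue_samples = pvalue_samples,
        seed = if (is.null(seed)) NULL else seed + cand_counter)
    }
    reps <- c(reps, select_representatives(cands))
  }
  reps <- dedupe_longest(reps)
  table <- if (length(reps))
    do.call(rbind, lapply(reps, .candidate_row))
  else .candidate_row_empty()
  rownames(table) <- NULL
  structure(list(table = table, candidates = reps,
                 stats = list(hits_in = n_in, hits_kept = nrow(hits),
                              groups = length(groups),
                              candidates = cand_counter,
                              representatives = length(reps))),
            class = "bridge_set")
}

.candidate_row_empty <- function() {
  cols <- c("theme_id", "domain_a", "domain_b", "xgroup_a", "xgroup_b")
  out <- data.frame(matrix(character(0), 0, 5, dimnames = list(NULL, cols)),
                    stringsAsFactors = FALSE)
  for (nm in c("start_a", "end_a", "start_b", "end_b")) out[[nm]] <- integer(0)
  out$mode <- character(0)
  for (nm in c("score", "n_aligned", "pct_identity", "pct_similarity",
               "p_value", "before_n", "before_id", "before_score",
               "after_n", "after_id", "after_score")) out[[nm]] <- numeric(0)
  out$flank_pass_before <- logical(0)
  out$flank_pass_after <- logical(0)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bridge_set <- function(x, ...) {
  s <- x$stats
  cat("<bridge_set> ", s$representatives, " representative candidate(s) ",
      "from ", s$groups, " theme/X-group pair group(s)\n", sep = "")
  cat("  hits: ", s$hits_kept, "/", s$hits_in, " kept; ",
      s$candidates, " candidate alignment(s)\n", sep = "")
  invisible(x)
}

#' Write / read the bridge table
#' @param bridges A `bridge_set` or its `table` data.frame.
#' @param path Output path.
#' @export
write_bridges <- function(bridges, path) {
  tab <- if (inherits(bridges, "bridge_set")) bridges$table else bridges
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bridges
#' @export
read_bridges <- function(path) {
  read.table(path, sep = "\t", header = TRUE, quote = "",
             colClasses = NA, stringsAsFactors = FALSE,
             comment.char = "")
}
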