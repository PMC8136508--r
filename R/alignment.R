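#' Pairwise sequence alignment with affine gaps
#'
#' Thin interface over [Biostrings::pairwiseAlignment()] returning the
#' statistics used throughout the pipeline: the aligned residue index pairs,
#' the raw score, the number of aligned (non-gap) columns `n_aligned`, and
#' percent identity / percent similarity computed over the aligned columns
#' (similarity = substitution score > 0, the usual "positives" definition).
#' A gap of length k costs `gap_open + k * gap_extend`.
#'
#' `smith_waterman()` computes the optimal local alignment (score floored at
#' 0; the all-negative case yields an empty alignment), `needleman_wunsch()`
#' the optimal global alignment with end gaps penalized.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings over the 20-letter
#'   alphabet plus `X`.
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Affine gap parameters (default 11 / 1, the
#'   standard pairing for BLOSUM62).
#' @return An object of class `theme_alignment`: a list with `pairs`
#'   (two-column integer matrix of aligned 1-based positions, strictly
#'   increasing in both columns), `score`, `n_aligned`, `pct_identity`,
#'   `pct_similarity`, `mode`, `gap_open`, `gap_extend`.
#' @export
smith_waterman <- function(seq_a, seq_b, matrix = blosum62(),
                           gap_open = 11, gap_extend = 1) {
  align_pair(seq_a, seq_b, mode = "local", matrix = matrix,
             gap_open = gap_open, gap_extend = gap_extend)
}

#' @rdname smith_waterman
#' @export
needleman_wunsch <- function(seq_a, seq_b, matrix = blosum62(),
                             gap_open = 11, gap_extend = 1) {
  align_pair(seq_a, seq_b, mode = "global", matrix = matrix,
             gap_open = gap_open, gap_extend = gap_extend)
}

.check_alpha <- function(seq, matrix, arg) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) < 1)
    stop(arg, " must be a non-empty string")
  bad <- setdiff(strsplit(seq, "")[[1]], rownames(matrix))
  if (length(bad))
    stop(arg, " contains symbols outside the substitution-matrix alphabet: ",
         paste(bad, collapse = ""))
}

#' @rdname smith_waterman
#' @param mode `"local"` (Smith-Waterman) or `"global"` (Needleman-Wunsch).
#' @export
align_pair <- function(seq_a, seq_b, mode = c("local", "global"),
                       matrix = blosum62(), gap_open = 11, gap_extend = 1) {
  mode <- match.arg(mode)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  .check_alpha(seq_a, matrix, "seq_a")
  .check_alpha(seq_b, matrix, "seq_b")
  al <- Biostrings::pairwiseAlignment(
    pattern = seq_a, subject = seq_b,
    type = mode, substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  score <- Biostrings::score(al)
  pa <- as.character(Biostrings::alignedPattern(al))
  sa <- as.character(Biostrings::alignedSubject(al))
  if (mode == "local" && score <= 0) {
    return(.empty_alignment(mode, gap_open, gap_extend))
  }
  i0 <- Biostrings::start(Biostrings::pattern(al)) - 1L
  j0 <- Biostrings::start(Biostrings::subject(al)) - 1L
  pc <- strsplit(pa, "")[[1]]
  sc <- strsplit(sa, "")[[1]]
  ii <- i0 + cumsum(pc != "-")
  jj <- j0 + cumsum(sc != "-")
  both <- pc != "-" & sc != "-"
  pairs <- cbind(i = ii[both], j = jj[both])
  ra <- pc[both]; rb <- sc[both]
  n <- nrow(pairs)
  pct_id <- if (n) 100 * mean(ra == rb) else NA_real_
  pct_sim <- if (n) 100 * mean(matrix[cbind(ra, rb)] > 0) else NA_real_
  structure(list(pairs = pairs, score = score, n_aligned = n,
                 pct_identity = pct_id, pct_similarity = pct_sim,
                 mode = mode, gap_open = gap_open, gap_extend = gap_extend),
            class = "theme_alignment")
}

.empty_alignment <- function(mode, gap_open, gap_extend) {
  structure(list(pairs = cbind(i = integer(0), j = integer(0)),
                 score = 0, n_aligned = 0L,
                 pct_identity = NA_real_, pct_similarity = NA_real_,
                 mode = mode, gap_open = gap_open, gap_extend = gap_extend),
            class = "theme_alignment")
}

#' @export
print.theme_alignment <- function(x, ...) {
  cat("<theme_alignment> mode=", x$mode, " score=", x$score,
      " aligned=", x$n_aligned, sep = "")
  if (x$n_aligned > 0)
    cat(sprintf("  id=%.1f%%  sim=%.1f%%", x$pct_identity, x$pct_similarity))
  cat("\n")
  invisible(x)
}

#' Fit a Gumbel (extreme value) distribution by maximum likelihood
#'
#' Location `mu` and scale `beta` are estimated by the standard fixed-point
#' iteration for the scale (method-of-moments initialisation), with
#' method-of-moments values used as a fallback on non-convergence.
#'
#' @param x Numeric sample (length >= 2, non-degenerate).
#' @param tol,max_iter Convergence controls for the scale iteration.
#' @return List with `mu`, `beta`, `n_samples`, `converged`.
#' @export
fit_gumbel <- function(x, tol = 1e-10, max_iter = 200) {
  stopifnot(length(x) >= 2)
  s <- sd(x)
  if (s == 0) stop("degenerate sample: zero variance")
  beta <- s * sqrt(6) / pi
  mom <- beta
  converged <- FALSE
  xc <- x - max(x)  # center for numerical stability of exp()
  for (it in seq_len(max_iter)) {
    w <- exp(-xc / beta)
    beta_new <- mean(x) - sum(x * w) / sum(w)
    if (!is.finite(beta_new) || beta_new <= 0) break
    if (abs(beta_new - beta) < tol) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  if (!converged) beta <- mom
  mu <- max(x) - beta * log(mean(exp(-xc / beta)))
  list(mu = mu, beta = beta, n_samples = length(x), converged = converged)
}

#' Significance of an alignment score against a composition-preserving null
#'
#' Draws `n_samples` random sequences of the same length as `seq_b` from the
#' residue composition of `seq_b` (multinomial with an add-one pseudocount
#' over the 20 standard amino acids), aligns each to `seq_a` with the same
#' aligner and parameters that produced `observed_score`, fits a Gumbel
#' distribution to the null scores by maximum likelihood, and reports
#' `p = 1 - exp(-exp(-(S - mu)/beta))`.
#'
#' If the null score sample has zero variance the fit is degenerate and `p`
#' is reported as 1 when `S <= mu` and 0 otherwise, with `degenerate = TRUE`.
#'
#' @inheritParams smith_waterman
#' @param observed_score Score whose significance is assessed (must come from
#'   the same aligner, matrix and gap parameters).
#' @param mode Alignment mode used for the observed score.
#' @param n_samples Number of null sequences (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `p_value`, `fit` (as from [fit_gumbel()], or the
#'   degenerate location) and `degenerate`.
#' @export
alignment_pvalue <- function(seq_a, seq_b, observed_score,
                             mode = c("local", "global"),
                             matrix = blosum62(), gap_open = 11,
                             gap_extend = 1, n_samples = 1000, seed = NULL) {
  mode <- match.arg(mode)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  .check_alpha(seq_a, matrix, "seq_a")
  .check_alpha(seq_b, matrix, "seq_b")
  if (!is.null(seed)) set.seed(seed)
  alpha <- intersect(rownames(matrix), AA20)
  comp <- table(factor(strsplit(seq_b, "")[[1]], levels = alpha))
  freq <- (as.numeric(comp) + 1) / (sum(comp) + length(alpha))
  len <- nchar(seq_b)
  rand <- vapply(seq_len(n_samples), function(k)
    paste(sample(alpha, len, replace = TRUE, prob = freq), collapse = ""),
    character(1))
  scores <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::BStringSet(rand), subject = seq_a,
    type = mode, substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
  if (mode == "local") scores <- pmax(scores, 0)
  if (sd(scores) == 0) {
    mu <- scores[1]
    warning("degenerate null score sample (zero variance)")
    return(list(p_value = if (observed_score <= mu) 1 else 0,
                fit = list(mu = mu, beta = NA_real_,
                           n_samples = n_samples, converged = FALSE),
                degenerate = TRUE))
  }
  fit <- fit_gumbel(scores)
  z <- (observed_score - fit$mu) / fit$beta
  p <- -expm1(-exp(-z))
  list(p_value = p, fit = fit, degenerate = FALSE)
}
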