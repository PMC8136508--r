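#' Optimal rigid superposition (Kabsch) and C-alpha RMSD
#'
#' Least-squares rigid-body superposition of two equal-length coordinate
#' sets via the SVD-based Kabsch algorithm, reflection-free. The returned
#' rotation and translation map `coords_a` onto `coords_b`.
#'
#' @param coords_a,coords_b Numeric n x 3 matrices, n >= 3.
#' @return List with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (Angstrom).
#' @export
superpose_rmsd <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in length")
  if (nrow(a) < 3) stop("at least 3 atom pairs are required")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  h <- crossprod(a0, b0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- a0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b0)^2)))
  list(rotation = rot, translation = cb - as.numeric(rot %*% ca),
       rmsd = rmsd)
}

#' Distance RMSD between two conformations
#'
#' Superposition-free measure: the root mean square difference of all
#' intramolecular pairwise distances, over the n(n-1)/2 pairs i < j.
#'
#' @param coords_a,coords_b Numeric n x 3 matrices, n >= 2.
#' @return dRMSD in Angstrom.
#' @export
drmsd <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in length")
  if (nrow(a) < 2) stop("at least 2 atom pairs are required")
  da <- dist(a); db <- dist(b)
  sqrt(mean((da - db)^2))
}

#' Percent contact-map change between two conformations
#'
#' Two residues are in contact when their contact atoms (conventionally
#' C-beta, C-alpha for glycine) are closer than `threshold` Angstrom. Both
#' l x l 0/1 maps are built over the same aligned residue pairs and the
#' fraction of differing entries, out of all l^2 entries (diagonal
#' included; it never differs), is returned as a percentage.
#'
#' @param coords_a,coords_b Numeric l x 3 matrices of contact-atom
#'   coordinates for the aligned residue pairs.
#' @param threshold Contact distance threshold in Angstrom (conventionally
#'   9 or 11).
#' @return Percentage of differing contact-map entries.
#' @export
contact_map_change <- function(coords_a, coords_b, threshold = 9) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in length")
  l <- nrow(a)
  if (l == 0) stop("no aligned residues")
  cm <- function(m) as.matrix(dist(m)) < threshold
  100 * sum(cm(a) != cm(b)) / l^2
}

## 8-state DSSP alphabet -> 3 states (helix / strand / coil)
ss_to3 <- function(chars) {
  out <- rep("C", length(chars))
  out[chars %in% c("H", "G", "I")] <- "H"
  out[chars %in% c("E", "B")] <- "E"
  out
}

#' Percent secondary-structure agreement over aligned residue pairs
#'
#' 8-state DSSP assignments are mapped to 3 states (H,G,I -> helix;
#' E,B -> strand; everything else -> coil) and the percentage of aligned
#' pairs with equal 3-state labels is reported. Pairs whose residues lack an
#' assignment on either side are skipped and counted.
#'
#' @param ss_a,ss_b Per-residue secondary-structure strings of the two
#'   domains.
#' @param pairs Two-column matrix of aligned 1-based residue indices.
#' @return List with `pct_agreement`, `n_used`, `n_skipped`.
#' @export
ss_agreement <- function(ss_a, ss_b, pairs) {
  pairs <- as.matrix(pairs)
  ca <- strsplit(ss_a, "")[[1]]; cb <- strsplit(ss_b, "")[[1]]
  ok <- pairs[, 1] >= 1 & pairs[, 1] <= length(ca) &
    pairs[, 2] >= 1 & pairs[, 2] <= length(cb)
  a3 <- ss_to3(ca[pairs[ok, 1]])
  b3 <- ss_to3(cb[pairs[ok, 2]])
  list(pct_agreement = if (sum(ok)) 100 * mean(a3 == b3) else NA_real_,
       n_used = sum(ok), n_skipped = sum(!ok))
}

#' Classify a theme pair as structurally similar or dissimilar
#'
#' @param rmsd C-alpha RMSD in Angstrom.
#' @param threshold Similarity threshold (default 6 Angstrom); values
#'   strictly below are "similar", the boundary itself is "dissimilar".
#' @return `"similar"` or `"dissimilar"`.
#' @export
classify_similarity <- function(rmsd, threshold = 6.0) {
  stopifnot(rmsd >= 0)
  ifelse(rmsd < threshold, "similar", "dissimilar")
}

## pick per-residue atom coordinates from a coords table; NA rows when absent
.atom_xyz <- function(coords, residues, atom) {
  sel <- coords[coords$atom == atom, , drop = FALSE]
  idx <- match(residues, sel$res_index)
  cbind(sel$x[idx], sel$y[idx], sel$z[idx])
}

## contact atoms: C-beta, falling back to C-alpha (glycine or missing CB)
.contact_xyz <- function(coords, residues) {
  cb <- .atom_xyz(coords, residues, "CB")
  ca <- .atom_xyz(coords, residues, "CA")
  miss <- is.na(cb[, 1])
  cb[miss, ] <- ca[miss, ]
  cb
}

#' Structural divergence metrics for one aligned theme pair
#'
#' Computes, over the aligned residue pairs that have coordinates on both
#' sides: C-alpha RMSD after optimal superposition, dRMSD, percent
#' contact-map change at the two thresholds, secondary-structure agreement
#' (when assignments are available), and the similar/dissimilar class.
#'
#' @param record_a,record_b [domain_record()]s with `coords` present.
#' @param pairs Two-column matrix of aligned domain-level residue indices.
#' @param contact_thresholds Numeric pair of contact thresholds (default
#'   `c(9, 11)` Angstrom).
#' @param rmsd_threshold Similarity classification threshold (default 6).
#' @return List of class `structure_metrics` with `rmsd_ca`, `drmsd`,
#'   `cm_change_9`, `cm_change_11`, `ss_agreement`, `n_used`, `similar`.
#' @export
candidate_structure_metrics <- function(record_a, record_b, pairs,
                                        contact_thresholds = c(9, 11),
                                        rmsd_threshold = 6.0) {
  if (is.null(record_a$coords) || is.null(record_b$coords))
    stop("both domains need coordinates")
  pairs <- as.matrix(pairs)
  ca_a <- .atom_xyz(record_a$coords, pairs[, 1], "CA")
  ca_b <- .atom_xyz(record_b$coords, pairs[, 2], "CA")
  ok <- !is.na(ca_a[, 1]) & !is.na(ca_b[, 1])
  n_used <- sum(ok)
  if (n_used < 3)
    stop("fewer than 3 aligned residue pairs with coordinates")
  ca_a <- ca_a[ok, , drop = FALSE]; ca_b <- ca_b[ok, , drop = FALSE]
  rmsd <- superpose_rmsd(ca_a, ca_b)$rmsd
  dr <- drmsd(ca_a, ca_b)
  cb_a <- .contact_xyz(record_a$coords, pairs[ok, 1])
  cb_b <- .contact_xyz(record_b$coords, pairs[ok, 2])
  cm1 <- contact_map_change(cb_a, cb_b, contact_thresholds[1])
  cm2 <- contact_map_change(cb_a, cb_b, contact_thresholds[2])
  ssa <- if (!is.null(record_a$ss) && !is.null(record_b$ss))
    ss_agreement(record_a$ss, record_b$ss, pairs[ok, , drop = FALSE])
  else list(pct_agreement = NA_real_, n_used = 0L, n_skipped = 0L)
  structure(list(rmsd_ca = rmsd, drmsd = dr,
                 cm_change_9 = cm1, cm_change_11 = cm2,
                 ss_agreement = ssa$pct_agreement, n_used = n_used,
                 similar = rmsd < rmsd_threshold),
            class = "structure_metrics")
}

#' Structural metrics for every representative bridge candidate
#'
#' Converts each candidate's theme alignment into domain-level residue
#' pairs (by offsetting with the hit intervals) and computes
#' [candidate_structure_metrics()] against the given domain records.
#' Candidates whose domains lack coordinates are reported with `NA` metrics.
#'
#' @param bridges A `bridge_set` from [detect_bridges()].
#' @param records Named list of [domain_record()]s with coordinates (and
#'   optionally `ss`).
#' @param contact_thresholds,rmsd_threshold See
#'   [candidate_structure_metrics()].
#' @return data.frame with one row per candidate: ids, `rmsd_ca`, `drmsd`,
#'   `cm_change_9`, `cm_change_11`, `ss_agreement`, `n_used`, `class`.
#' @export
compute_structure_metrics <- function(bridges, records,
                                      contact_thresholds = c(9, 11),
                                      rmsd_threshold = 6.0) {
  stopifnot(inherits(bridges, "bridge_set"))
  rows <- lapply(bridges$candidates, function(cand) {
    pairs <- cand$theme_aln$pairs
    pairs <- cbind(pairs[, 1] + cand$hit_a$start - 1L,
                   pairs[, 2] + cand$hit_b$start - 1L)
    ra <- records[[cand$domain_a]]; rb <- records[[cand$domain_b]]
    m <- tryCatch(
      candidate_structure_metrics(ra, rb, pairs, contact_thresholds,
                                  rmsd_threshold),
      error = function(e) NULL)
    data.frame(theme_id = cand$theme_id, domain_a = cand$domain_a,
               domain_b = cand$domain_b, mode = cand$theme_aln$mode,
               rmsd_ca = if (is.null(m)) NA_real_ else m$rmsd_ca,
               drmsd = if (is.null(m)) NA_real_ else m$drmsd,
               cm_change_9 = if (is.null(m)) NA_real_ else m$cm_change_9,
               cm_change_11 = if (is.null(m)) NA_real_ else m$cm_change_11,
               ss_agreement = if (is.null(m)) NA_real_ else m$ss_agreement,
               n_used = if (is.null(m)) NA_integer_ else m$n_used,
               class = if (is.null(m)) NA_character_ else
                 classify_similarity(m$rmsd_ca, rmsd_threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(theme_id = character(0), domain_a = character(0),
                      domain_b = character(0), mode = character(0),
                      rmsd_ca = numeric(0), drmsd = numeric(0),
                      cm_change_9 = numeric(0), cm_change_11 = numeric(0),
                      ss_agreement = numeric(0), n_used = integer(0),
                      class = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit a two-component Gaussian mixture to theme RMSD values
#'
#' Univariate EM with 2-means initialisation (10 seeded restarts).
#' Convergence when the log-likelihood improves by less than `tol`
#' (default 1e-8) or after `max_iter` (default 500) iterations; the
#' log-likelihood trace is retained and is non-decreasing. Components are
#' reported in ascending order of mean, so the first component is the
#' structurally similar (low-RMSD) one.
#'
#' @param rmsds Numeric vector of RMSD values (>= 10, non-degenerate).
#' @param seed Optional seed for the initialisation.
#' @param max_iter,tol Convergence controls.
#' @return Object of class `rmsd_mixture`: `weights`, `means`, `sds`,
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `n`.
#' @export
fit_rmsd_mixture <- function(rmsds, seed = NULL, max_iter = 500,
                             tol = 1e-8) {
  x <- as.numeric(rmsds)
  x <- x[is.finite(x)]
  if (length(x) < 10) stop("at least 10 RMSD values are required")
  if (sd(x) == 0) stop("degenerate input: all RMSD values identical")
  if (!is.null(seed)) set.seed(seed)
  km <- kmeans(x, centers = 2, nstart = 10)
  mu <- as.numeric(km$centers)
  w <- as.numeric(table(factor(km$cluster, levels = 1:2))) / length(x)
  s <- vapply(1:2, function(k) {
    v <- sd(x[km$cluster == k])
    if (is.na(v) || v < 1e-3) sd(x) / 2 else v
  }, 1)
  loglik_trace <- numeric(0)
  ll_old <- -Inf; converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    dens <- cbind(w[1] * dnorm(x, mu[1], s[1]),
                  w[2] * dnorm(x, mu[2], s[2]))
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_))
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r <- dens / rowsum_
    nk <- colSums(r)
    w <- nk / length(x)
    mu <- colSums(r * x) / nk
    s <- sqrt(pmax(colSums(r * (outer(x, mu, `-`))^2) / nk, 1e-6))
  }
  ord <- order(mu)
  structure(list(weights = w[ord], means = mu[ord], sds = s[ord],
                 loglik = loglik_trace[length(loglik_trace)],
                 loglik_trace = loglik_trace, n_iter = it,
                 converged = converged, n = length(x)),
            class = "rmsd_mixture")
}

#' @export
print.rmsd_mixture <- function(x, ...) {
  cat("<rmsd_mixture> two-component Gaussian fit, n =", x$n, "\n")
  cat(sprintf("  similar:    weight %.2f, mean %.2f A (sd %.2f)\n",
              x$weights[1], x$means[1], x$sds[1]))
  cat(sprintf("  dissimilar: weight %.2f, mean %.2f A (sd %.2f)\n",
              x$weights[2], x$means[2], x$sds[2]))
  cat(sprintf("  loglik %.3f after %d iteration(s)%s\n", x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.rmsd_mixture <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.rmsd_mixture <- function(x, data = NULL, breaks = 30, ...) {
  xx <- seq(max(0, x$means[1] - 4 * x$sds[1]),
            x$means[2] + 4 * x$sds[2], length.out = 400)
  dens <- x$weights[1] * dnorm(xx, x$means[1], x$sds[1]) +
    x$weights[2] * dnorm(xx, x$means[2], x$sds[2])
  if (!is.null(data)) {
    graphics::hist(data, breaks = breaks, freq = FALSE,
                   xlab = "theme RMSD (A)", main = "RMSD mixture", ...)
    graphics::lines(xx, dens, lwd = 2)
  } else {
    graphics::plot(xx, dens, type = "l", lwd = 2, xlab = "theme RMSD (A)",
                   ylab = "density", main = "RMSD mixture", ...)
  }
  graphics::abline(v = x$means, lty = 2)
  invisible(x)
}
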