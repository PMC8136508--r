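# Independent plain-R affine-gap alignment oracle (Gotoh three-state DP),
# written without reference to the package's alignment route. A gap of
# length k costs open + k * ext. Local scores are floored at zero; global
# alignment penalizes end gaps. Only the optimal score is produced.
oracle_align_score <- function(a, b, mat, open = 11, ext = 1,
                               mode = c("local", "global")) {
  mode <- match.arg(mode)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # last column aligned residue-residue
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (a residue vs gap)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a
  if (mode == "global") {
    M[1, 1] <- 0
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  best_local <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      diag_best <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- diag_best + s
      if (mode == "local") M[i + 1, j + 1] <- max(M[i + 1, j + 1], s, 0)
      X[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                             X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                             Y[i + 1, j] - ext)
      if (mode == "local")
        best_local <- max(best_local, M[i + 1, j + 1])
    }
  }
  if (mode == "local") best_local
  else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}
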