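rotmat <- function(ax, ay, az) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

test_that("Kabsch superposition is exact on rigidly moved copies", {
  set.seed(41)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_rmsd(a, a)$rmsd, 0, tolerance = 1e-12)

  b <- a %*% t(rotmat(0, 0, pi / 2)) + matrix(c(3, -1, 7), 10, 3,
                                              byrow = TRUE)
  expect_lt(superpose_rmsd(a, b)$rmsd, 1e-9)
  expect_error(superpose_rmsd(a[1:2, ], b[1:2, ]), "3")

  # colinear degenerate sets do not crash
  line <- cbind(1:5, 0, 0)
  expect_lt(superpose_rmsd(line, line + 2)$rmsd, 1e-9)
})

test_that("superposed RMSD matches an exhaustive rotation-grid oracle", {
  # unit square vs unit square with one corner displaced (planar sets:
  # the optimal rotation is in-plane, so a fine 1D angle grid is exhaustive)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  sq2 <- sq; sq2[3, ] <- c(1, 2, 0)
  grid_oracle <- function(a, b) {
    a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
    min(vapply(seq(0, 2 * pi, length.out = 100000), function(th) {
      r <- rotmat(0, 0, th)
      sqrt(mean(rowSums((a0 %*% t(r) - b0)^2)))
    }, 1))
  }
  expect_equal(superpose_rmsd(sq, sq2)$rmsd, grid_oracle(sq, sq2),
               tolerance = 1e-6)
})

test_that("Kabsch agrees with an established reference implementation", {
  set.seed(42)
  a <- matrix(rnorm(45), 15, 3)
  b <- a + matrix(rnorm(45, sd = 1.5), 15, 3)
  ours <- superpose_rmsd(a, b)$rmsd
  ref <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)  # bio3d rounds to 3 digits
})

test_that("dRMSD is superposition-free and matches the hand calculation", {
  set.seed(43)
  a <- matrix(rnorm(24), 8, 3)
  expect_equal(drmsd(a, a), 0)
  moved <- a %*% t(rotmat(0.3, 1.1, -0.4)) + 5
  expect_lt(drmsd(a, moved), 1e-9)

  # 3-point toy where exactly one of the three pair distances changes by 1:
  # dRMSD = sqrt(1/3)
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  q <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3.75), 0))
  expect_equal(drmsd(p, q), sqrt(1 / 3), tolerance = 1e-12)
  expect_error(drmsd(p[1, , drop = FALSE], q[1, , drop = FALSE]), "2")
})

test_that("rigid-motion invariance of RMSD and dRMSD holds to 1e-8", {
  set.seed(44)
  for (k in 1:10) {
    a <- matrix(rnorm(36), 12, 3)
    b <- matrix(rnorm(36), 12, 3)
    r <- rotmat(runif(1, 0, pi), runif(1, 0, pi), runif(1, 0, pi))
    bt <- b %*% t(r) + matrix(runif(3, -10, 10), 12, 3, byrow = TRUE)
    expect_lt(abs(superpose_rmsd(a, b)$rmsd - superpose_rmsd(a, bt)$rmsd),
              1e-8)
    expect_lt(abs(drmsd(a, b) - drmsd(a, bt)), 1e-8)
  }
})

test_that("contact-map change matches exhaustive pair enumeration", {
  set.seed(45)
  a <- matrix(rnorm(12, sd = 6), 4, 3)
  b <- matrix(rnorm(12, sd = 6), 4, 3)
  expect_equal(contact_map_change(a, a, 9), 0)
  for (thr in c(9, 11)) {
    # brute-force count over all ordered index pairs incl. the diagonal
    diffs <- 0
    for (i in 1:4) for (j in 1:4) {
      ca <- sqrt(sum((a[i, ] - a[j, ])^2)) < thr
      cb <- sqrt(sum((b[i, ] - b[j, ])^2)) < thr
      if (ca != cb) diffs <- diffs + 1
    }
    expect_equal(contact_map_change(a, b, thr), 100 * diffs / 16)
  }
  # extreme case: all contacts vs none (off-diagonal entries all differ)
  tight <- matrix(0.1 * (1:9), 3, 3)
  loose <- diag(3) * 1000
  expect_equal(contact_map_change(tight, loose, 9), 100 * 6 / 9)
})

test_that("secondary-structure agreement maps 8 states to 3 and skips gaps", {
  pairs <- cbind(1:7, 1:7)
  expect_equal(ss_agreement("HHHHHHH", "HHHHHHH", pairs)$pct_agreement, 100)
  expect_equal(ss_agreement("HHHHHHH", "EEEEEEE", pairs)$pct_agreement, 0)
  r <- ss_agreement("HHHECCC", "HHHHCCC", pairs)
  expect_equal(r$pct_agreement, 100 * 6 / 7, tolerance = 1e-12)
  # G/I count as helix, B as strand, T/S as coil
  expect_equal(ss_agreement("GIH", "HHH", cbind(1:3, 1:3))$pct_agreement, 100)
  expect_equal(ss_agreement("BTS", "ECC", cbind(1:3, 1:3))$pct_agreement, 100)
  # out-of-range pairs are skipped and counted
  r2 <- ss_agreement("HH", "HHH", cbind(1:3, 1:3))
  expect_equal(r2$n_used, 2)
  expect_equal(r2$n_skipped, 1)
})

test_that("similarity classification uses a strict 6 Angstrom boundary", {
  expect_equal(classify_similarity(3.3), "similar")
  expect_equal(classify_similarity(9.8), "dissimilar")
  expect_equal(classify_similarity(6.0), "dissimilar")
  expect_error(classify_similarity(-1))
})

test_that("planted conformation pairs classify as expected from geometry", {
  theme <- sample_ancestor(40, seed = 51)
  hx1 <- build_domain(theme, "ACDEF", "GHIKL", "dh1", "1.101.1.1.1",
                      conformation = "helix", seed = 52)
  hx2 <- build_domain(theme, "MNPQR", "STVWY", "dh2", "3.2004.1.1.1",
                      conformation = "helix", seed = 53)
  st1 <- build_domain(theme, "ACDEF", "GHIKL", "ds1", "2.300.1.1.1",
                      conformation = "strand", seed = 54)
  pairs <- cbind(6:45, 6:45)  # theme residues in both domains
  m_hh <- candidate_structure_metrics(hx1$record, hx2$record, pairs)
  m_he <- candidate_structure_metrics(hx1$record, st1$record, pairs)
  expect_true(m_hh$similar)       # identical helix templates
  expect_lt(m_hh$rmsd_ca, 1e-6)
  expect_false(m_he$similar)      # helix vs extended strand
  expect_gt(m_he$rmsd_ca, 6)
  expect_equal(m_he$ss_agreement, 0)
  expect_equal(m_hh$ss_agreement, 100)
  # near-identical theme backbones: drmsd ~ 0; contact maps agree except
  # possibly at the theme boundary, where pseudo C-beta directions depend
  # on flanking residues
  expect_lt(m_hh$drmsd, 1e-9)
  expect_lt(m_hh$cm_change_9, 1)
  expect_lt(m_hh$cm_change_11, 1)
  # identical coordinate sets give exactly zero change at any threshold
  ca <- as.matrix(hx1$record$coords[hx1$record$coords$atom == "CA",
                                    c("x", "y", "z")])
  expect_equal(contact_map_change(ca, ca, 9), 0)
  expect_equal(contact_map_change(ca, ca, 11), 0)
})

test_that("the RMSD mixture EM recovers parameters and increases loglik", {
  set.seed(61)
  x <- c(rnorm(1400, 3.3, 1.0), rnorm(3600, 9.8, 2.0))
  fit <- fit_rmsd_mixture(x, seed = 62)
  expect_true(fit$converged)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$means) > 0))
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))  # EM monotonicity
  expect_equal(fit$weights[1], 0.28, tolerance = 0.03)
  expect_equal(fit$means[1], 3.3, tolerance = 0.2)
  expect_equal(fit$means[2], 9.8, tolerance = 0.2)

  expect_error(fit_rmsd_mixture(rep(5, 20)), "degenerate")
  expect_error(fit_rmsd_mixture(c(1, 2, 3)), "at least 10")

  # single-cluster input: returns without error, convergence status reported
  y <- rnorm(300, 5, 1)
  fit1 <- fit_rmsd_mixture(y, seed = 63)
  expect_true(is.logical(fit1$converged))
  expect_true(all(diff(fit1$loglik_trace) >= -1e-8))
})

test_that("the EM fit agrees with an independent mixture implementation", {
  withr::local_package("mclust")  # Mclust needs its namespace attached
  set.seed(64)
  x <- c(rnorm(500, 3, 1), rnorm(1000, 10, 2))
  ours <- fit_rmsd_mixture(x, seed = 65)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(ours$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.1)
  expect_equal(ours$loglik, ref$loglik, tolerance = 1)
})
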