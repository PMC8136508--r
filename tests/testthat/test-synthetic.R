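test_that("ancestor sampling is reproducible and respects frequencies", {
  s1 <- sample_ancestor(49, seed = 1)
  s2 <- sample_ancestor(49, seed = 1)
  expect_equal(s1, s2)
  expect_equal(nchar(s1), 49)
  expect_error(sample_ancestor(0), ">= 1")
  expect_error(sample_ancestor(10, aa_frequencies = c(A = 0.5, C = 0.4)),
               "sum to 1")

  # skewed composition: observed A-fraction within 3 binomial SDs of 0.5
  freqs <- setNames(c(0.5, rep(0.5 / 19, 19)),
                    c("A", setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                            "")[[1]], "A")))
  s <- sample_ancestor(10000, aa_frequencies = freqs, seed = 3)
  fA <- mean(strsplit(s, "")[[1]] == "A")
  expect_lt(abs(fA - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("variation evolution preserves length and hits the target identity", {
  anc <- sample_ancestor(2000, seed = 5)
  expect_equal(evolve_variation(anc, 0), anc)

  v1 <- evolve_variation(anc, 1, seed = 6)
  expect_equal(nchar(v1), nchar(anc))
  id1 <- mean(strsplit(v1, "")[[1]] == strsplit(anc, "")[[1]])
  expect_equal(id1, 0)  # substitution always picks a different residue

  v <- evolve_variation(anc, 0.3, seed = 7)
  id <- mean(strsplit(v, "")[[1]] == strsplit(anc, "")[[1]])
  expect_lt(abs(id - 0.7), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("planted pair identity at rate 0.2 lands in the expected band", {
  # two independent variations at rate r agree with probability
  # (1-r)^2 + r^2/19 under the uniform background
  set.seed(8)
  ids <- replicate(100, {
    anc <- sample_ancestor(49)
    a <- strsplit(evolve_variation(anc, 0.2), "")[[1]]
    b <- strsplit(evolve_variation(anc, 0.2), "")[[1]]
    mean(a == b)
  })
  expected <- 0.8^2 + 0.2^2 / 19
  se <- sd(ids) / sqrt(length(ids))
  expect_lt(abs(mean(ids) - expected), 3 * se)
})

test_that("toy backbones have ideal geometry and conformation-dependent SS", {
  theme <- sample_ancestor(30, seed = 9)
  h <- build_domain(theme, "ACDEF", "GHIKL", conformation = "helix",
                    seed = 10)
  e <- build_domain(theme, "ACDEF", "GHIKL", conformation = "strand",
                    seed = 11)
  # same sequence, different conformation: SS differs over the theme
  expect_equal(h$record$sequence, e$record$sequence)
  expect_equal(substr(h$record$ss, 6, 35), strrep("H", 30))
  expect_equal(substr(e$record$ss, 6, 35), strrep("E", 30))

  # consecutive C-alpha distances all within [3.7, 3.9] Angstrom
  for (built in list(h, e)) {
    co <- built$record$coords
    ca <- as.matrix(co[co$atom == "CA", c("x", "y", "z")])
    steps <- sqrt(rowSums(diff(ca)^2))
    expect_true(all(steps >= 3.7 & steps <= 3.9))
  }
})

test_that("planted ligands sit within reach of the designated theme residue", {
  theme <- sample_ancestor(30, seed = 12)
  built <- build_domain(theme, "ACDEF", "GHIKL", conformation = "helix",
                        ligand = TRUE, ligand_site = 15, seed = 13)
  expect_false(is.null(built$ligand))
  res <- binding_residues(built$record$coords, built$ligand, cutoff = 4.5)
  expect_true(built$ligand_site %in% res)
  # multi-atom cluster variant
  b4 <- build_domain(theme, "", "", conformation = "strand", ligand = TRUE,
                     multi_atom = TRUE, seed = 14)
  expect_equal(nrow(b4$ligand$atoms), 4)
  d <- as.matrix(dist(b4$ligand$atoms[, c("x", "y", "z")]))
  expect_equal(unname(d[upper.tri(d)]), rep(2.2, 6), tolerance = 1e-8)

  expect_error(build_domain("", ""), "non-empty")
})

test_that("the benchmark is reproducible and internally consistent", {
  bm <- get_benchmark()
  # truth and hit tables mutually consistent: every planted interval is a hit
  for (i in seq_len(nrow(bm$truth))) {
    tr <- bm$truth[i, ]
    match_ <- bm$hits[bm$hits$theme_id == tr$theme_id &
                        bm$hits$domain_id == tr$domain_id &
                        bm$hits$start == tr$start &
                        bm$hits$end == tr$end, ]
    expect_equal(nrow(match_), 1)
    expect_equal(match_$e_value, 1e-6)
  }
  # planted pairs span different X-groups
  cls <- read_classification(bm$paths$classification)
  for (t in unique(bm$truth$theme_id)) {
    doms <- bm$truth$domain_id[bm$truth$theme_id == t]
    expect_equal(length(unique(xgroup_of(cls[doms]))), 2)
  }
  # decoys all sit above the downstream E-value threshold
  decoys <- bm$hits[bm$hits$e_value > 1e-6, ]
  expect_true(all(decoys$e_value > 1e-3))

  # reproducibility: the same config yields byte-identical outputs
  dir2 <- file.path(tempdir(), "bt_bench_repro")
  cfg <- plant_config(n_xgroups = 6, domains_per_group = 2, n_themes = 4,
                      ligand_fraction = 1, seed = 42)
  generate_benchmark(cfg, dir2)
  for (f in c("domains.fasta", "classification.tsv", "hits.tsv",
              "truth.tsv", "ss.tsv")) {
    expect_equal(readLines(file.path(dir2, f)),
                 readLines(file.path(get_benchmark_dir(), f)),
                 info = f)
  }
  unlink(dir2, recursive = TRUE)
})

test_that("a 2x1 configuration plants exactly one cross-group pair", {
  dir <- withr::local_tempdir()
  cfg <- plant_config(n_xgroups = 2, domains_per_group = 1, n_themes = 1,
                      seed = 3)
  bm <- generate_benchmark(cfg, dir)
  expect_equal(nrow(bm$truth), 2)          # one theme in two domains
  expect_equal(length(unique(bm$truth$theme_id)), 1)
})

test_that("partner flanks are as dissimilar as random-sequence background", {
  bm <- get_benchmark()
  flank_scores <- c()
  lens <- list()
  for (t in unique(bm$truth$theme_id)) {
    tr <- bm$truth[bm$truth$theme_id == t, ]
    sa <- bm$records[[tr$domain_id[1]]]$sequence
    sb <- bm$records[[tr$domain_id[2]]]$sequence
    ca <- split_context(sa, tr$start[1], tr$end[1])
    cb <- split_context(sb, tr$start[2], tr$end[2])
    for (side in c("before", "after")) {
      flank_scores <- c(flank_scores,
                        smith_waterman(ca[[side]], cb[[side]])$score)
      lens[[length(lens) + 1]] <- c(nchar(ca[[side]]), nchar(cb[[side]]))
    }
  }
  # matched-length random background
  set.seed(77)
  bg <- replicate(60, {
    l <- lens[[sample(length(lens), 1)]]
    smith_waterman(rand_seq(l[1]), rand_seq(l[2]))$score
  })
  se <- sd(bg) / sqrt(length(bg)) + sd(flank_scores) / sqrt(length(flank_scores))
  expect_lt(abs(mean(flank_scores) - mean(bg)), 3 * max(se, 1))
})
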