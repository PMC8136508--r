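make_hit <- function(theme_id = "t1", domain_id = "d1", start = 1L,
                     end = 20L, e_value = 1e-5, coverage = 0.9) {
  data.frame(theme_id = theme_id, domain_id = domain_id, start = start,
             end = end, e_value = e_value, coverage = coverage,
             stringsAsFactors = FALSE)
}

test_that("hit filtering applies both thresholds", {
  hits <- rbind(make_hit(e_value = 1e-4, coverage = 0.9),
                make_hit(e_value = 1e-2, coverage = 0.9),
                make_hit(e_value = 1e-4, coverage = 0.5))
  kept <- filter_hits(hits)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$e_value, 1e-4)
  expect_equal(kept$coverage, 0.9)
  expect_equal(nrow(filter_hits(hits[0, ])), 0)
})

test_that("cross-group pairing partitions by X-group and counts candidates", {
  cls <- c(d1 = "1.101.1.1.1", d2 = "3.2004.1.1.1", d3 = "3.2004.2.1.1",
           a1 = "1.101.1.1.1", a2 = "1.101.1.1.2",
           b1 = "3.2004.1.1.1", b2 = "3.2004.1.1.2", b3 = "3.2004.1.1.3")
  g <- cross_group_pairs(rbind(make_hit("t1", "d1"), make_hit("t1", "d2")),
                         cls)
  expect_length(g, 1)
  expect_equal(g[[1]]$n1, 1)
  expect_equal(g[[1]]$n2, 1)
  expect_equal(g[[1]]$xgroups, c("101", "2004"))

  # same X-group only: no group
  g2 <- cross_group_pairs(rbind(make_hit("t1", "d2"), make_hit("t1", "d3")),
                          cls)
  expect_length(g2, 0)

  # 2 + 3 domains across two X-groups: n1 * n2 = 6 candidates
  h <- rbind(make_hit("t1", "a1"), make_hit("t1", "a2"),
             make_hit("t1", "b1"), make_hit("t1", "b2"),
             make_hit("t1", "b3"))
  g3 <- cross_group_pairs(h, cls)
  expect_length(g3, 1)
  expect_equal(g3[[1]]$n1 * g3[[1]]$n2, 6)

  # unclassified domain dropped with a warning
  expect_warning(
    g4 <- cross_group_pairs(rbind(make_hit("t1", "d1"),
                                  make_hit("t1", "zz")), cls),
    "unclassified")
  expect_length(g4, 0)

  # duplicate hits of one theme on one domain: lowest E-value wins
  h5 <- rbind(make_hit("t1", "d1", e_value = 1e-4, start = 1, end = 20),
              make_hit("t1", "d1", e_value = 1e-8, start = 5, end = 25),
              make_hit("t1", "d2"))
  g5 <- cross_group_pairs(h5, cls)
  expect_equal(g5[[1]]$n1, 1)
  ha <- rbind(g5[[1]]$hits_a, g5[[1]]$hits_b)
  expect_equal(ha$e_value[ha$domain_id == "d1"], 1e-8)
})

test_that("context splitting partitions the sequence exactly", {
  s <- strrep("A", 100)
  ctx <- split_context(s, 31, 70)  # [30, 70) on disk
  expect_equal(nchar(ctx$before), 30)
  expect_equal(nchar(ctx$theme), 40)
  expect_equal(nchar(ctx$after), 30)
  expect_equal(paste0(ctx$before, ctx$theme, ctx$after), s)

  ctx2 <- split_context(s, 1, 50)
  expect_equal(ctx2$before, "")
  ctx3 <- split_context(s, 1, 100)
  expect_equal(ctx3$before, "")
  expect_equal(ctx3$after, "")
  expect_error(split_context(s, 0, 50), "out of range")
  expect_error(split_context(s, 90, 101), "out of range")
})

test_that("the flank filter passes on short or dissimilar alignments", {
  aln <- function(n, id) {
    structure(list(pairs = cbind(seq_len(n), seq_len(n)), score = 10,
                   n_aligned = n, pct_identity = id, pct_similarity = id,
                   mode = "local", gap_open = 11, gap_extend = 1),
              class = "theme_alignment")
  }
  expect_true(flank_filter(aln(10, 40), aln(10, 40))[["before"]])  # short
  expect_true(flank_filter(aln(30, 20), aln(30, 20))[["after"]])   # dissimilar
  fp <- flank_filter(aln(30, 30), aln(10, 40))
  expect_false(fp[["before"]])  # long and similar: context not different
  expect_true(fp[["after"]])
})

test_that("candidate alignment uses SW, falling back to NW for short locals", {
  set.seed(31)
  cls_a <- "1.101.1.1.1"; cls_b <- "3.2004.1.1.1"
  # planted-style pair: long similar theme -> local mode
  anc <- sample_ancestor(49)
  rec_a <- domain_record("da", paste0(rand_seq(25),
                                      evolve_variation(anc, 0.2),
                                      rand_seq(25)), cls_a)
  rec_b <- domain_record("db", paste0(rand_seq(30),
                                      evolve_variation(anc, 0.2),
                                      rand_seq(20)), cls_b)
  cand <- align_candidate(rec_a, rec_b,
                          make_hit("t1", "da", 26, 74),
                          make_hit("t1", "db", 31, 79),
                          pvalue_samples = 200, seed = 3)
  expect_s3_class(cand, "bridge_candidate")
  expect_equal(cand$theme_aln$mode, "local")
  expect_gt(cand$theme_aln$n_aligned, 20)
  expect_lt(cand$p_value, 0.01)

  # a theme whose local alignment is trimmed short -> global fallback
  core <- "ACDEFGHIKLMNPQRSTVW"
  noise_a <- paste0(strrep("W", 15), core)
  noise_b <- paste0(strrep("P", 15), core)
  rec_c <- domain_record("dc", noise_a, cls_a)
  rec_d <- domain_record("dd", noise_b, cls_b)
  cand2 <- align_candidate(rec_c, rec_d,
                           make_hit("t2", "dc", 1, nchar(noise_a)),
                           make_hit("t2", "dd", 1, nchar(noise_b)),
                           pvalue_samples = 0)
  expect_equal(smith_waterman(noise_a, noise_b)$n_aligned, 19)
  expect_equal(cand2$theme_aln$mode, "global")
})

test_that("representative selection maximises theme-vs-flank contrast", {
  fake_cand <- function(id_a, id_b, theme_score, flank_score, e = 1e-5) {
    aln <- function(score) structure(
      list(pairs = cbind(1:5, 1:5), score = score, n_aligned = 5L,
           pct_identity = 50, pct_similarity = 60, mode = "local",
           gap_open = 11, gap_extend = 1), class = "theme_alignment")
    structure(list(theme_id = "t1", domain_a = id_a, domain_b = id_b,
                   xgroup_a = "101", xgroup_b = "2004",
                   hit_a = make_hit("t1", id_a, e_value = e),
                   hit_b = make_hit("t1", id_b, e_value = e),
                   theme_aln = aln(theme_score),
                   before_aln = aln(flank_score), after_aln = aln(flank_score),
                   flank_pass_before = TRUE, flank_pass_after = TRUE,
                   p_value = NA_real_), class = "bridge_candidate")
  }
  single <- list(fake_cand("a1", "b1", 50, 10))
  expect_identical(select_representatives(single), single)

  # the candidate with max theme score and min flank score ranks first
  cands <- list(fake_cand("a1", "b1", 100, 5),
                fake_cand("a1", "b2", 60, 30),
                fake_cand("a2", "b1", 55, 35),
                fake_cand("a2", "b2", 50, 40),
                fake_cand("a3", "b1", 45, 45),
                fake_cand("a3", "b2", 40, 50))
  reps <- select_representatives(cands)
  expect_length(reps, 2)
  expect_equal(reps[[1]]$domain_a, "a1")
  expect_equal(reps[[1]]$domain_b, "b1")
  expect_true(all(vapply(reps, function(r)
    any(vapply(cands, identical, logical(1), r)), logical(1))))

  # all-equal scores: zero SD handled, deterministic lexicographic tie-break
  eq <- list(fake_cand("a2", "b1", 50, 10), fake_cand("a1", "b1", 50, 10),
             fake_cand("a1", "b2", 50, 10))
  reps2 <- select_representatives(eq)
  expect_equal(vapply(reps2, function(r) paste(r$domain_a, r$domain_b), ""),
               c("a1 b1", "a1 b2"))

  # lower E-value breaks ties before the id pair
  ev <- list(fake_cand("a2", "b1", 50, 10, e = 1e-4),
             fake_cand("a1", "b1", 50, 10, e = 1e-3))
  expect_equal(select_representatives(ev)[[1]]$domain_a, "a2")
})

test_that("per-domain-pair deduplication keeps the longest theme", {
  fake <- function(theme, a, b, n, score) {
    aln <- structure(list(pairs = cbind(seq_len(n), seq_len(n)),
                          score = score, n_aligned = n, pct_identity = 50,
                          pct_similarity = 60, mode = "local",
                          gap_open = 11, gap_extend = 1),
                     class = "theme_alignment")
    structure(list(theme_id = theme, domain_a = a, domain_b = b,
                   hit_a = make_hit(theme, a), hit_b = make_hit(theme, b),
                   theme_aln = aln), class = "bridge_candidate")
  }
  out <- dedupe_longest(list(fake("t1", "x", "y", 30, 80),
                             fake("t2", "y", "x", 45, 70)))
  expect_length(out, 1)
  expect_equal(out[[1]]$theme_id, "t2")

  # distinct pairs untouched
  out2 <- dedupe_longest(list(fake("t1", "x", "y", 30, 80),
                              fake("t2", "x", "z", 25, 70)))
  expect_length(out2, 2)

  # equal length: higher score wins
  out3 <- dedupe_longest(list(fake("t1", "x", "y", 30, 80),
                              fake("t2", "x", "y", 30, 90)))
  expect_equal(out3[[1]]$theme_id, "t2")
})

test_that("detection is a pure function of inputs and seed", {
  bm <- get_benchmark()
  cls <- read_classification(bm$paths$classification)
  seqs <- read_fasta(bm$paths$fasta)
  b1 <- detect_bridges(seqs, bm$hits, cls, pvalue_samples = 50, seed = 5)
  b2 <- detect_bridges(seqs, bm$hits, cls, pvalue_samples = 50, seed = 5)
  expect_identical(b1$table, b2$table)
  expect_equal(b1$stats$representatives, nrow(b1$table))
  # representatives are planted pairs only
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  truth_pairs <- unique(key(bm$truth$domain_id,
                            bm$truth$partner))
  expect_setequal(key(b1$table$domain_a, b1$table$domain_b), truth_pairs)
})
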