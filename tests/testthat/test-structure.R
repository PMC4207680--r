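plateau_coverage <- function(len, conds, start, end, depth, strand = "+") {
  cov <- mk_coverage(c(chr = len), paste0("c", seq_len(conds)))
  for (k in seq_len(conds))
    cov <- set_depth(cov, paste0("c", k), strand, "chr", start, end, depth)
  cov
}

test_that("an intergenic plateau meeting all thresholds is reported exactly", {
  g <- annotated_genome(c(chr = 2000L))
  cov <- plateau_coverage(2000L, 4, 600, 850, 6)   # 250 bp, depth 6
  nov <- find_novel_transcripts(g, cov)
  expect_equal(nrow(nov), 1L)
  expect_equal(nov$start, 600L)
  expect_equal(nov$end, 850L)
  expect_equal(nov$klass, "intergenic")
  expect_equal(nov$n_supporting_conditions, 4L)
})

test_that("plateaus of 200 bp are rejected and 201 bp accepted", {
  g <- annotated_genome(c(chr = 2000L))
  expect_equal(nrow(find_novel_transcripts(
    g, plateau_coverage(2000L, 3, 600, 800, 9))), 0L)   # exactly 200 bp
  out <- find_novel_transcripts(g, plateau_coverage(2000L, 3, 600, 801, 9))
  expect_equal(out$length, 201L)                        # 201 bp passes
})

test_that("thresholds on depth and condition count are enforced", {
  g <- annotated_genome(c(chr = 2000L))
  # depth 4 everywhere: never qualifies
  expect_equal(nrow(find_novel_transcripts(
    g, plateau_coverage(2000L, 3, 600, 900, 4))), 0L)
  # only 2 of 4 conditions covered
  cov <- mk_coverage(c(chr = 2000L), paste0("c", 1:4))
  cov <- set_depth(cov, "c1", "+", "chr", 600, 900, 8)
  cov <- set_depth(cov, "c2", "+", "chr", 600, 900, 8)
  expect_equal(nrow(find_novel_transcripts(g, cov)), 0L)
  # all-zero coverage
  expect_equal(nrow(find_novel_transcripts(
    g, mk_coverage(c(chr = 2000L), paste0("c", 1:3)))), 0L)
})

test_that("a 1-base dropout splits a transcript unless smoothing is enabled", {
  g <- annotated_genome(c(chr = 2000L))
  cov <- plateau_coverage(2000L, 3, 500, 1100, 7)
  for (k in 1:3) cov$depth[[k]]$`+`$chr[800] <- 0L   # dropout at one base
  split_ <- find_novel_transcripts(g, cov)
  expect_equal(nrow(split_), 2L)
  expect_equal(split_$end[1], 799L)
  joined <- find_novel_transcripts(g, cov, smooth = 2)
  expect_equal(nrow(joined), 1L)
})

test_that("same-strand annotation masks the scan; opposite strand classifies antisense", {
  g <- annotated_genome(c(chr = 2000L),
                        feature_df("host", "chr", 500, 1100, "-"))
  # plateau fully inside the opposite-strand gene -> antisense
  cov <- plateau_coverage(2000L, 3, 600, 900, 8, strand = "+")
  nov <- find_novel_transcripts(g, cov)
  expect_equal(nov$klass, "antisense")
  expect_equal(nov$opposite_gene, "host")
  # same plateau on the gene's own strand is masked away
  cov2 <- plateau_coverage(2000L, 3, 600, 900, 8, strand = "-")
  expect_equal(nrow(find_novel_transcripts(g, cov2)), 0L)
  # under 50% overlap stays intergenic
  g3 <- annotated_genome(c(chr = 2000L),
                         feature_df("edge", "chr", 820, 1500, "-"))
  nov3 <- find_novel_transcripts(g3, cov)   # overlap 80/300 = 27%
  expect_equal(nov3$klass, "intergenic")
})

test_that("the scanner matches the per-position extension oracle", {
  withr::local_seed(31)
  for (rep in 1:8) {
    L <- 1500L
    n_feat <- sample(0:2, 1)
    feats <- if (n_feat > 0) {
      st <- sort(sample(seq(0, 1200, 50), n_feat))
      feature_df(paste0("f", seq_len(n_feat)), "chr", st, st + 120, "+")
    } else empty_features()
    g <- annotated_genome(c(chr = L), feats)
    cov <- mk_coverage(c(chr = L), paste0("c", 1:4))
    for (k in 1:4) {
      v <- integer(L)
      for (b in 1:6) {
        at <- sample(1:(L - 400), 1)
        v[at:(at + sample(150:400, 1))] <- sample(3:8, 1)
      }
      cov$depth[[k]]$`+`$chr <- v
    }
    got <- find_novel_transcripts(g, cov, min_conditions = 2)
    mask <- rep(TRUE, L)
    for (i in seq_len(nrow(feats))) mask[(feats$start[i] + 1):feats$end[i]] <- FALSE
    okmat <- sapply(1:4, function(k) cov$depth[[k]]$`+`$chr >= 5 & mask)
    orc <- oracle_scan(okmat, 2L, 201L)
    expect_equal(nrow(got), nrow(orc))
    if (nrow(orc)) {
      expect_equal(got$start, unname(orc[, "start"]))
      expect_equal(got$end, unname(orc[, "end"]))
    }
  }
})

tu_fixture <- function(gap, r2 = 1, strand = "+", npeaks = NULL) {
  # two tandem genes with controllable gap and profile correlation
  g <- annotated_genome(c(chr = 10000L), rbind(
    feature_df("g1", "chr", 1000, 2000, strand),
    feature_df("g2", "chr", 2000 + gap, 3000 + gap, strand)))
  x <- c(1, 2, 3, 4, 5)
  y <- if (r2 == 1) x else with_exact_cor(x, r2, z = c(1, -1, 0, -1, 1)) + 2
  expr <- rbind(g1 = x, g2 = y)
  colnames(expr) <- paste0("c", 1:5)
  calls <- NULL
  if (!is.null(npeaks))
    calls <- data.frame(gene = npeaks, status = "confirmed",
                        peak_pos = NA_integer_, offset = 0L, support = 20L)
  list(genome = g, expr = expr, calls = calls)
}

test_that("tandem co-expressed genes chain into one TU", {
  fx <- tu_fixture(gap = 100)
  tus <- find_operons(fx$genome, fx$expr)
  expect_equal(nrow(tus$tus), 1L)
  expect_equal(tus$members[[1]], c("g1", "g2"))
})

test_that("gaps of 149 bp chain and 150 bp break", {
  expect_equal(nrow(find_operons(tu_fixture(149)$genome,
                                 tu_fixture(149)$expr)$tus), 1L)
  expect_equal(nrow(find_operons(tu_fixture(150)$genome,
                                 tu_fixture(150)$expr)$tus), 2L)
  expect_equal(nrow(find_operons(tu_fixture(200)$genome,
                                 tu_fixture(200)$expr)$tus), 2L)
})

test_that("profile correlation of exactly 0.6 breaks and 0.61 chains", {
  # integer profiles with exact Pearson r = 3/5
  g <- tu_fixture(100)$genome
  expr_06 <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = c(2, 1, 5, 3, 4))
  colnames(expr_06) <- paste0("c", 1:5)
  expect_equal(cor(expr_06["g1", ], expr_06["g2", ]), 0.6)
  expect_equal(nrow(find_operons(g, expr_06)$tus), 2L)
  fx61 <- tu_fixture(100, r2 = 0.61)
  expect_equal(nrow(find_operons(fx61$genome, fx61$expr)$tus), 1L)
})

test_that("an internal reliable 5' peak breaks a TU", {
  fx <- tu_fixture(100, npeaks = "g2")           # peak on the downstream gene
  expect_equal(nrow(find_operons(fx$genome, fx$expr,
                                 list(calls = fx$calls))$tus), 2L)
  fx_lead <- tu_fixture(100, npeaks = "g1")      # leader peak is fine
  expect_equal(nrow(find_operons(fx_lead$genome, fx_lead$expr,
                                 list(calls = fx_lead$calls))$tus), 1L)
})

test_that("minus-strand TUs are split below their rightmost leader", {
  # on the minus strand the leader is the genomically last gene
  fx <- tu_fixture(100, strand = "-", npeaks = "g2")
  expect_equal(nrow(find_operons(fx$genome, fx$expr,
                                 list(calls = fx$calls))$tus), 1L)
  expect_equal(find_operons(fx$genome, fx$expr,
                            list(calls = fx$calls))$members[[1]],
               c("g2", "g1"))
  fx2 <- tu_fixture(100, strand = "-", npeaks = "g1")  # interior on minus
  expect_equal(nrow(find_operons(fx2$genome, fx2$expr,
                                 list(calls = fx2$calls))$tus), 2L)
})

test_that("TU inference partitions the gene set", {
  tus <- default_run$tus
  all_members <- unlist(tus$members)
  cds <- default_sim$genome$features$id
  expect_setequal(all_members, cds)
  expect_equal(anyDuplicated(all_members), 0L)
})

test_that("feature-set comparison applies the 40% shorter-feature rule", {
  ours <- feature_df("a", "chr", 100, 200, "+")
  res <- compare_feature_sets(ours, feature_df("b", "chr", 150, 250, "+"))
  expect_equal(unname(res$counts["agree"]), 1)      # overlap 50/100 = 0.5
  res2 <- compare_feature_sets(ours, feature_df("b", "chr", 170, 300, "+"))
  expect_equal(unname(res2$counts["agree"]), 0)     # overlap 30/100 = 0.3
  expect_equal(unname(res2$counts[c("ours_only", "theirs_only")]), c(1, 1))
  # strand must agree
  res3 <- compare_feature_sets(ours, feature_df("b", "chr", 150, 250, "-"))
  expect_equal(unname(res3$counts["agree"]), 0)
})

test_that("identical feature sets match completely", {
  set_ <- feature_df(c("a", "b"), "chr", c(0, 500), c(300, 900),
                     c("+", "-"))
  res <- compare_feature_sets(set_, set_)
  expect_equal(unname(res$counts), c(2, 0, 0, 0))
})

test_that("TU comparison separates exact membership from partial agreement", {
  ours <- feature_df(c("t1", "t2"), "chr", c(0, 1000), c(500, 1600), "+")
  theirs <- feature_df(c("u1", "u2"), "chr", c(0, 1000), c(500, 1600), "+")
  res <- compare_feature_sets(
    ours, theirs,
    ours_members = list(t1 = c("g1", "g2"), t2 = c("g3", "g4")),
    theirs_members = list(u1 = c("g1", "g2"), u2 = c("g3", "g5")))
  expect_equal(unname(res$counts["agree"]), 1)
  expect_equal(unname(res$counts["differ"]), 1)
})
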