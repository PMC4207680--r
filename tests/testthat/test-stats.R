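mk_counts <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("ref", "trt")[seq_len(ncol(m))]
  m
}

test_that("identical counts give p = 1 and no call", {
  cts <- mk_counts(g1 = c(50, 50), g2 = c(0, 0))
  de <- de_test(cts, c("ref", "trt"), c(ref = 1e6, trt = 1e6))
  expect_equal(de$p, c(1, 1))
  expect_equal(de$log2fc, c(0, 0))
  expect_false(any(de$called))
})

test_that("the dispersion-0 limit equals the exact binomial conditional test", {
  cts <- mk_counts(g1 = c(10, 40))
  de <- de_test(cts, c("ref", "trt"), c(ref = 1e6, trt = 1e6), dispersion = 0)
  pr <- dbinom(0:50, 50, 0.5)
  oracle <- sum(pr[pr <= pr[11] * (1 + 1e-7)])
  expect_equal(de$p, oracle)
  expect_equal(de$log2fc, log2(40.5 / 10.5))
})

test_that("the exact NB test is calibrated at its own dispersion", {
  # null simulation: independent NB counts at the test's dispersion; the
  # fraction of p < 0.01 must stay below 1.5%
  withr::local_seed(41)
  n <- 10000
  cts <- cbind(ref = rnbinom(n, size = 1 / 0.1, mu = 200),
               trt = rnbinom(n, size = 1 / 0.1, mu = 200))
  rownames(cts) <- paste0("g", 1:n)
  de <- de_test(cts, c("ref", "trt"), c(ref = 1e6, trt = 1e6),
                dispersion = 0.1)
  expect_lte(mean(de$p < 0.01), 0.015)
})

test_that("library-size scaling enters the fold change and the test", {
  cts <- mk_counts(g1 = c(100, 200))
  de_eq <- de_test(cts, c("ref", "trt"), c(ref = 1e6, trt = 1e6))
  # doubling the treatment library exactly explains the doubled count
  de_lib <- de_test(cts, c("ref", "trt"), c(ref = 1e6, trt = 2e6))
  expect_lt(abs(de_lib$log2fc), abs(de_eq$log2fc))
  expect_gt(de_lib$p, de_eq$p)
})

test_that("rescue by pathway requires similar same-sign fold changes", {
  g <- annotated_genome(c(chr = 10000L), rbind(
    feature_df("seed", "chr", 0, 1000, "+", pathway = "pwA"),
    feature_df("close", "chr", 2000, 3000, "+", pathway = "pwA"),
    feature_df("opposite", "chr", 4000, 5000, "+", pathway = "pwA"),
    feature_df("far_lfc", "chr", 6000, 7000, "+", pathway = "pwA"),
    feature_df("other_pw", "chr", 8000, 9000, "+", pathway = "pwB")))
  de <- data.frame(
    gene = c("seed", "close", "opposite", "far_lfc", "other_pw"),
    contrast = "trt vs ref",
    log2fc = c(3, 2.5, -3, 0.5, 3), p = 1e-6, p_adj = c(1e-5, 1, 1, 1, 1),
    called = c(TRUE, FALSE, FALSE, FALSE, FALSE), rescue_reason = "none",
    stringsAsFactors = FALSE)
  out <- augment_de(de, g)
  expect_true(out$called[out$gene == "close"])
  expect_equal(out$rescue_reason[out$gene == "close"], "pathway")
  expect_false(out$called[out$gene == "opposite"])   # sign rule
  expect_false(out$called[out$gene == "far_lfc"])    # |delta lfc| > 1
  expect_false(out$called[out$gene == "other_pw"])
})

test_that("rescue by shared TU and the no-seed fixpoint", {
  g <- annotated_genome(c(chr = 10000L), rbind(
    feature_df("a", "chr", 0, 1000, "+"),
    feature_df("b", "chr", 1100, 2000, "+")))
  tus <- list(members = list(TU_1 = c("a", "b")))
  de <- data.frame(gene = c("a", "b"), contrast = "t vs r",
                   log2fc = c(4, 0.2), p = 1e-9, p_adj = c(1e-8, 0.4),
                   called = c(TRUE, FALSE), rescue_reason = "none",
                   stringsAsFactors = FALSE)
  out <- augment_de(de, g, tus)
  expect_true(out$called[2])
  expect_equal(out$rescue_reason[2], "tu")
  de_none <- de; de_none$called <- FALSE
  expect_identical(augment_de(de_none, g, tus), de_none)
})

test_that("enrichment p-values equal the hypergeometric summation oracle", {
  # universe of 100 genes: 10 called (5 in category), 90 uncalled (5 in)
  g <- annotated_genome(c(chr = 1000000L), feature_df(
    sprintf("g%03d", 1:100), "chr", seq(0, by = 10000, length.out = 100),
    seq(0, by = 10000, length.out = 100) + 5000, "+",
    cog = c(rep("C", 5), rep(NA, 5), rep("C", 5), rep(NA, 85))))
  de <- data.frame(gene = sprintf("g%03d", 1:100), contrast = "t vs r",
                   log2fc = 3, p = 1, p_adj = 1,
                   called = c(rep(TRUE, 10), rep(FALSE, 90)),
                   rescue_reason = "none", stringsAsFactors = FALSE)
  enr <- enrich_cog(de, g)
  up <- enr[enr$direction == "up" & enr$category == "C", ]
  expect_equal(up[, c("called_in", "called_out", "uncalled_in",
                      "uncalled_out")],
               data.frame(called_in = 5, called_out = 5, uncalled_in = 5,
                          uncalled_out = 85), ignore_attr = TRUE)
  expect_equal(up$p, oracle_fisher_p(5, 5, 5, 85), tolerance = 1e-10)
  # all genes called in one direction -> degenerate table, p = 1
  de2 <- de; de2$called <- TRUE
  enr2 <- enrich_cog(de2, g)
  expect_true(all(enr2$p[enr2$direction == "up"] == 1))
})

test_that("identical conditions merge first at height zero", {
  withr::local_seed(42)
  expr <- matrix(rexp(40), 10, 4,
                 dimnames = list(paste0("g", 1:10), c("a", "b", "c", "d")))
  expr[, "d"] <- expr[, "a"]
  cl <- cluster_conditions(expr)
  expect_equal(cl$merges$height[1], 0)
  expect_equal(cl$merges$members[1], "a,d")
})

test_that("constant condition columns are rejected by name", {
  expr <- matrix(c(1, 2, 3, 5, 5, 5, 2, 1, 4), 3,
                 dimnames = list(NULL, c("a", "flat", "c")))
  expect_error(cluster_conditions(expr), "flat")
})

test_that("clustering matches the naive complete-linkage oracle", {
  withr::local_seed(43)
  for (n in c(5, 6, 8)) {
    expr <- matrix(rnorm(20 * n), 20, n,
                   dimnames = list(paste0("g", 1:20), paste0("c", 1:n)))
    cl <- cluster_conditions(expr)
    D <- as.matrix(1 - cor(expr))
    orc <- oracle_complete_linkage(D)
    expect_equal(cl$merges$height,
                 vapply(orc, `[[`, numeric(1), "height"))
    expect_equal(cl$merges$members,
                 vapply(orc, function(s) paste(s$members, collapse = ","),
                        character(1)))
  }
})

test_that("clustering is invariant under condition permutation", {
  withr::local_seed(44)
  expr <- matrix(rnorm(20 * 6), 20, 6,
                 dimnames = list(paste0("g", 1:20), paste0("c", 1:6)))
  cl1 <- cluster_conditions(expr)
  perm <- sample(6)
  cl2 <- cluster_conditions(expr[, perm])
  m1 <- sort(cl1$merges$members)
  m2 <- sort(cl2$merges$members)
  expect_equal(m1, m2)
  expect_equal(sort(cl1$merges$height), sort(cl2$merges$height))
})

test_that("hypothetical proteins link to known genes above r = 0.9 only", {
  g <- annotated_genome(c(chr = 100000L), rbind(
    feature_df("hyp", "chr", 0, 1000, "+"),                  # no COG
    feature_df("twin", "chr", 2000, 3000, "+", cog = "C"),
    feature_df("near", "chr", 4000, 5000, "+", cog = "E"),
    feature_df("exact90", "chr", 6000, 7000, "+", cog = "F"),
    feature_df("r91", "chr", 8000, 9000, "+", cog = "G")))
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  withr::local_seed(45)
  expr <- rbind(hyp = x, twin = 2 * x + 1,
                near = with_exact_cor(x, 0.85) + 2,
                exact90 = with_exact_cor(x, 0.90) + 2,
                r91 = with_exact_cor(x, 0.91) + 2)
  colnames(expr) <- paste0("c", 1:8)
  links <- link_hypotheticals(expr, g)
  expect_equal(links$hypothetical, c("hyp", "hyp"))
  expect_equal(links$annotated, c("twin", "r91"))   # sorted by r, desc
  expect_equal(links$r[1], 1)
  # r = 0.85 and the exact-threshold r = 0.9 are excluded
  expect_false("near" %in% links$annotated)
  expect_false("exact90" %in% links$annotated)
  # no hypothetical genes -> empty result
  g2 <- annotated_genome(c(chr = 100000L),
                         feature_df("k", "chr", 0, 1000, "+", cog = "C"))
  expect_equal(nrow(link_hypotheticals(expr["twin", , drop = FALSE], g2)), 0L)
})

test_that("DE calls on the fixture respect BH monotonicity", {
  de <- default_run$de
  one <- de[de$contrast == de$contrast[1], ]
  ord <- order(one$p)
  expect_true(all(diff(one$p_adj[ord]) >= -1e-12))
  expect_true(all(one$p_adj >= one$p - 1e-12))
})
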