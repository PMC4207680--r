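test_that("Passing-Bablok recovers exact lines", {
  fit <- passing_bablok(c(1, 2, 3), c(1, 2, 3))
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  fit <- passing_bablok(1:5, 2 * (1:5) + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_error(passing_bablok(rep(2, 5), 1:5), "identical")
  expect_error(passing_bablok(1:2, 1:2), "3")
})

test_that("Passing-Bablok matches the all-pairs shifted-median oracle", {
  withr::local_seed(21)
  for (rep in 1:30) {
    n <- sample(5:30, 1)
    x <- rnorm(n, sd = 2)
    y <- sample(c(-1.5, 0.5, 2), 1) * x + rnorm(n)
    fit <- passing_bablok(x, y)
    orc <- oracle_pb(x, y)
    expect_equal(fit$slope, orc$slope)
    expect_equal(fit$intercept, orc$intercept)
  }
})

test_that("swapping x and y inverts the Passing-Bablok slope", {
  withr::local_seed(22)
  for (rep in 1:10) {
    x <- rnorm(25, sd = 2)
    y <- 1.7 * x + rnorm(25, sd = 0.5)
    b_xy <- passing_bablok(x, y)$slope
    b_yx <- passing_bablok(y, x)$slope
    # exact for an odd number of pairwise slopes; the even case averages two
    # adjacent order statistics, so inversion holds only to ~1e-5
    expect_equal(b_xy, 1 / b_yx, tolerance = 1e-3)
  }
})

test_that("peak calling keeps local maxima with at least 5 reads", {
  tr <- fiveprime_track(data.frame(
    contig = "chr", pos = c(10L, 12L, 14L, 100L, 300L, 304L),
    strand = c("+", "+", "+", "+", "-", "-"),
    support = c(6L, 20L, 6L, 4L, 9L, 9L)))
  pk <- call_peaks(tr)
  # stutter collapses to the maximum; support-4 dropped; tie keeps leftmost
  expect_equal(pk$pos, c(12L, 300L))
  expect_equal(pk$support, c(20L, 9L))
})

test_that("calibration set needs a COG and 150 bp of clear downstream space", {
  g <- annotated_genome(c(chr = 10000L), rbind(
    feature_df("ok", "chr", 1000, 2000, "+", cog = "C"),          # next at 2200
    feature_df("next1", "chr", 2200, 2600, "+", cog = "E"),       # crowded: 100 bp
    feature_df("no_cog", "chr", 4000, 4500, "+"),                 # clear but no COG
    feature_df("crowded", "chr", 5000, 5500, "+", cog = "C"),
    feature_df("next2", "chr", 5600, 6000, "+", cog = "E"),
    feature_df("minus_ok", "chr", 8000, 8500, "-", cog = "C")))
  ids <- build_calibration_set(g)
  expect_true("ok" %in% ids)          # 200 bp downstream clearance
  expect_true("minus_ok" %in% ids)
  expect_false("no_cog" %in% ids)
  expect_false("crowded" %in% ids)    # neighbour 100 bp downstream
  # opposite-strand neighbours do not block
  expect_true("next2" %in% ids)
})

noiseless_calibration <- function() {
  # genes with uniform depth 2^k and peak support exactly 2 * depth:
  # log-log line with slope 1, intercept log 2
  n <- 12
  starts <- seq(1000, by = 2000, length.out = n)
  g <- annotated_genome(c(chr = 30000L),
                        feature_df(sprintf("g%02d", 1:n), "chr", starts,
                                   starts + 1000, "+", cog = "C"))
  cov <- mk_coverage(c(chr = 30000L), "c1")
  lev <- round(2^seq(3, 6.5, length.out = n))
  for (i in 1:n)
    cov <- set_depth(cov, "c1", "+", "chr", starts[i], starts[i] + 1000,
                     lev[i])
  tr <- fiveprime_track(data.frame(contig = "chr", pos = as.integer(starts),
                                   strand = "+", support = 2L * lev))
  list(genome = g, coverage = cov, track = tr, levels = lev)
}

test_that("noiseless peaks recover the planted calibration line with r = 1", {
  fx <- noiseless_calibration()
  ids <- build_calibration_set(fx$genome)
  fit <- calibrate_peaks(fx$genome, fx$coverage, fx$track, ids)
  expect_true(fit$usable)
  expect_equal(fit$calibration_r, 1)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, log(2))
})

test_that("shuffled peak heights make the fit unusable", {
  withr::local_seed(23)
  fx <- noiseless_calibration()
  tr <- fx$track
  tr$support <- sample(tr$support)
  ids <- build_calibration_set(fx$genome)
  fit <- calibrate_peaks(fx$genome, fx$coverage, tr, ids)
  expect_false(fit$usable)
  expect_lt(abs(fit$calibration_r), 0.6)
  expect_match(fit$status, "correlation")
  expect_error(filter_reliable_peaks(tr, fit, fx$coverage), "usable")
})

test_that("too few calibration pairs yield an explicit unusable status", {
  fx <- noiseless_calibration()
  fit <- calibrate_peaks(fx$genome, fx$coverage, fx$track,
                         build_calibration_set(fx$genome)[1:3])
  expect_false(fit$usable)
  expect_match(fit$status, "pairs")
})

test_that("reliability filtering keeps in-band peaks and drops outliers", {
  fx <- noiseless_calibration()
  ids <- build_calibration_set(fx$genome)
  # mild noise so the residual band has width
  withr::local_seed(24)
  tr <- fx$track
  tr$support <- pmax(1L, as.integer(round(tr$support * exp(rnorm(nrow(tr), 0, 0.1)))))
  fit <- calibrate_peaks(fx$genome, fx$coverage, tr, ids)
  expect_true(fit$usable)
  g1 <- fx$genome$features[1, ]
  probe <- fiveprime_track(data.frame(
    contig = "chr", pos = g1$start, strand = "+",
    support = c(2L * fx$levels[1],        # on the line
                20L * 2L * fx$levels[1],  # 20x above the band
                4L)))                     # below the hard support floor
  kept <- filter_reliable_peaks(probe, fit, fx$coverage)
  expect_equal(kept$support, 2L * fx$levels[1])
  detail <- attr(kept, "detail")
  expect_equal(detail$reason[detail$support == 4], "low_support")
  expect_equal(detail$reason[detail$support == 20L * 2L * fx$levels[1]],
               "outside_band")
})

test_that("peak assignment reproduces the worked start-site cases", {
  g <- annotated_genome(c(chr = 10000L), rbind(
    feature_df("shift60", "chr", 1000, 2000, "+"),
    feature_df("up150", "chr", 4000, 5000, "+"),
    feature_df("far", "chr", 7000, 8000, "+")))
  tr <- fiveprime_track(data.frame(
    contig = "chr",
    pos = c(1060L,        # 60 bp inside the CDS -> shifted, offset 60
            3850L,        # 150 bp upstream -> confirmed
            6750L),       # 250 bp upstream -> beyond the 200 bp window
    strand = "+", support = 50L))
  res <- assign_peaks(g, tr)
  calls <- res$calls
  expect_equal(calls$status[calls$gene == "shift60"], "shifted")
  expect_equal(calls$offset[calls$gene == "shift60"], 60L)
  expect_equal(calls$status[calls$gene == "up150"], "confirmed")
  expect_equal(calls$status[calls$gene == "far"], "no_peak")
})

test_that("minus-strand offsets are strand-aware", {
  g <- annotated_genome(c(chr = 10000L),
                        feature_df("m", "chr", 1000, 2000, "-"))
  # 5' end at 1999; peak 60 bp downstream (leftward) at 1939
  tr <- fiveprime_track(data.frame(contig = "chr", pos = 1939L,
                                   strand = "-", support = 30L))
  calls <- assign_peaks(g, tr)$calls
  expect_equal(calls$status, "shifted")
  expect_equal(calls$offset, 60L)
})

test_that("peaks are never assigned across strands", {
  withr::local_seed(25)
  g <- annotated_genome(c(chr = 50000L), feature_df(
    sprintf("g%02d", 1:20), "chr", seq(1000, by = 2400, length.out = 20),
    seq(1000, by = 2400, length.out = 20) + 1200,
    rep(c("+", "-"), 10)))
  tr <- fiveprime_track(data.frame(
    contig = "chr", pos = sample.int(49000, 200), strand = "+",
    support = 10L))
  res <- assign_peaks(g, tr)
  hit <- g$features$strand[match(res$assignments$gene, g$features$id)]
  expect_true(all(hit == "+"))
})

test_that("genes with peaks at their annotated start are never called shifted", {
  # confirm tolerance 0: an exact-start peak must remain 'confirmed'
  s <- simulate_transcriptome(sim_config(
    seed = 11, contig_length = 80000L, n_genes = 50L, n_novel = 3L,
    n_antisense = 2L, n_start_shifts = 0L, outlier_peak_fraction = 0))
  pk <- call_peaks(s$track)
  ids <- build_calibration_set(s$genome)
  fit <- calibrate_peaks(s$genome, s$coverage, pk, ids)
  expect_true(fit$usable)
  reliable <- filter_reliable_peaks(pk, fit, s$coverage)
  calls <- assign_peaks(s$genome, reliable, confirm_tol = 0)$calls
  expect_equal(sum(calls$status == "shifted"), 0L)
})

test_that("most planted start shifts are recovered with their exact offset", {
  calls <- default_run$start_sites
  truth <- default_sim$truth$start_shifts
  hit <- calls[calls$gene %in% names(truth) & calls$status == "shifted", ]
  exact <- sum(hit$offset == truth[hit$gene])
  expect_gte(exact / length(truth), 0.8)
  # the 60 bp worked example is among the planted offsets and recovered
  g60 <- names(truth)[truth == 60][1]
  expect_equal(calls$offset[calls$gene == g60], 60L)
})
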