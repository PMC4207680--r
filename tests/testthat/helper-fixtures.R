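# Small constructors used across test files, plus the shared full-size
# synthetic fixture (built once per test run).

mk_coverage <- function(contigs, conditions, fill = 0L, totals = NULL) {
  depth <- lapply(conditions, function(cond)
    lapply(setNames(c("+", "-"), c("+", "-")), function(s)
      lapply(contigs, function(len) rep(as.integer(fill), len))))
  names(depth) <- conditions
  if (is.null(totals)) totals <- setNames(rep(1e6, length(conditions)),
                                          conditions)
  coverage_set(conditions, contigs, depth, totals)
}

set_depth <- function(cov, cond, strand, contig, start, end, value) {
  cov$depth[[cond]][[strand]][[contig]][(start + 1L):end] <-
    as.integer(value)
  cov
}

one_gene_genome <- function(len = 5000, gstart = 1000, gend = 2000,
                            strand = "+", cog = "C") {
  annotated_genome(c(chr = len),
                   feature_df("g1", "chr", gstart, gend, strand, cog = cog))
}

# vectors whose exact Pearson correlation with `x` is `r` (fp error ~1e-16)
with_exact_cor <- function(x, r, z = NULL) {
  xc <- x - mean(x)
  if (is.null(z)) {
    z <- rnorm(length(x))
    z <- z - mean(z)
    z <- z - sum(z * xc) / sum(xc^2) * xc
  }
  r * xc / sqrt(sum(xc^2)) + sqrt(1 - r^2) * z / sqrt(sum(z^2))
}

# shared default-size fixture: 200 kb, 150 genes, 11 conditions, fixed seed
default_sim <- simulate_transcriptome(sim_config(seed = 42))
default_run <- suppressMessages(
  run_pipeline(default_sim$genome, default_sim$coverage, default_sim$track))
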