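#' Reconstruct per-gene read counts from coverage
#'
#' The pipeline's inputs are per-base coverage tracks, not alignments, so
#' read counts are estimated as the summed per-base depth over the gene on
#' its own strand divided by the mean read length.  The conversion constant
#' cancels in every correlation-based downstream step.
#'
#' @param genome an [annotated_genome()]; only `CDS` features are counted
#'   unless `ftype = NULL`.
#' @param coverage a [coverage_set()].
#' @param read_length mean read length in bp.
#' @param ftype feature types to quantify.
#' @return numeric matrix genes x conditions of estimated read counts.
#' @export
gene_counts <- function(genome, coverage, read_length = 76, ftype = "CDS") {
  feats <- genome$features
  if (!is.null(ftype)) feats <- feats[feats$ftype %in% ftype, , drop = FALSE]
  if (!nrow(feats)) stop("no features to quantify")
  if (any(feats$end - feats$start < 1L)) stop("zero-length feature")
  counts <- matrix(0, nrow(feats), length(coverage$conditions),
                   dimnames = list(feats$id, coverage$conditions))
  for (j in seq_along(coverage$conditions)) {
    cond <- coverage$conditions[j]
    for (i in seq_len(nrow(feats))) {
      v <- depth_vector(coverage, cond, feats$strand[i], feats$contig[i],
                        feats$start[i], feats$end[i])
      counts[i, j] <- sum(v) / read_length
    }
  }
  counts
}

#' RPKM expression matrix
#'
#' RPKM (reads per kilobase of transcript per million mapped reads):
#' `rpkm[g, c] = reads[g, c] / (length_kb(g) * total_mapped(c) / 1e6)`, with
#' reads estimated from coverage via [gene_counts()].
#'
#' @inheritParams gene_counts
#' @return numeric matrix genes x conditions of RPKM values (class
#'   `rpkm_matrix`).
#' @export
rpkm_matrix <- function(genome, coverage, read_length = 76, ftype = "CDS") {
  feats <- genome$features
  if (!is.null(ftype)) feats <- feats[feats$ftype %in% ftype, , drop = FALSE]
  counts <- gene_counts(genome, coverage, read_length, ftype)
  if (any(coverage$total_mapped <= 0)) stop("total_mapped must be positive")
  len_kb <- (feats$end - feats$start)[match(rownames(counts), feats$id)] / 1000
  mill <- coverage$total_mapped[colnames(counts)] / 1e6
  out <- sweep(counts / len_kb, 2, mill, "/")
  class(out) <- c("rpkm_matrix", class(out))
  out
}

#' Cross-condition consistency of per-base expression profiles
#'
#' For every gene, the Spearman correlation of its per-base depth profile is
#' computed between every pair of conditions; the per-gene minimum is
#' reported.  Genes whose minimum is <= `flag_at`, or for which any pair is
#' undefined (an all-tied profile in some condition), are flagged for review.
#'
#' @inheritParams gene_counts
#' @param flag_at flag genes whose minimum pairwise rho is at or below this.
#' @return data.frame with columns `gene`, `min_rho` (NA when undefined for
#'   all pairs), `n_undefined` (condition pairs with undefined rho) and
#'   `flagged`.
#' @export
profile_consistency <- function(genome, coverage, flag_at = 0.5,
                                ftype = "CDS") {
  if (length(coverage$conditions) < 2L)
    stop("profile consistency needs >= 2 conditions")
  feats <- genome$features
  if (!is.null(ftype)) feats <- feats[feats$ftype %in% ftype, , drop = FALSE]
  res <- lapply(seq_len(nrow(feats)), function(i) {
    prof <- vapply(coverage$conditions, function(cond)
      as.numeric(depth_vector(coverage, cond, feats$strand[i],
                              feats$contig[i], feats$start[i], feats$end[i])),
      numeric(feats$end[i] - feats$start[i]))
    ranked <- apply(prof, 2, rank)
    rho <- suppressWarnings(cor(ranked))   # Spearman = Pearson on ranks
    pairs <- rho[upper.tri(rho)]
    n_na <- sum(is.na(pairs))
    min_rho <- if (all(is.na(pairs))) NA_real_ else min(pairs, na.rm = TRUE)
    data.frame(gene = feats$id[i], min_rho = min_rho, n_undefined = n_na,
               flagged = n_na > 0 || is.na(min_rho) || min_rho <= flag_at)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fraction of the genome (or of coding bases) covered by expression
#'
#' A position counts as covered when its depth reaches `min_depth` in any
#' condition on either strand (`genome_covered_fraction`) or in any condition
#' on the gene's own strand (`coding_covered_fraction`).
#'
#' @param coverage a [coverage_set()].
#' @param min_depth minimum per-base depth; the genome-wide default 3 reads
#'   "more than two reads" strictly, the coding default is 2.
#' @return a single fraction in \[0, 1\].
#' @export
genome_covered_fraction <- function(coverage, min_depth = 3) {
  covered <- 0; total <- 0
  for (ctg in names(coverage$contigs)) {
    len <- coverage$contigs[[ctg]]
    hit <- logical(len)
    for (cond in coverage$conditions)
      for (s in c("+", "-"))
        hit <- hit | (coverage$depth[[cond]][[s]][[ctg]] >= min_depth)
    covered <- covered + sum(hit)
    total <- total + len
  }
  covered / total
}

#' @rdname genome_covered_fraction
#' @param genome an [annotated_genome()] defining the coding bases.
#' @param ftype feature types counted as coding.
#' @export
coding_covered_fraction <- function(genome, coverage, min_depth = 2,
                                    ftype = "CDS") {
  feats <- genome$features
  if (!is.null(ftype)) feats <- feats[feats$ftype %in% ftype, , drop = FALSE]
  if (!nrow(feats)) stop("no coding features")
  covered <- 0; total <- 0
  for (ctg in unique(feats$contig)) {
    for (s in c("+", "-")) {
      sub <- feats[feats$contig == ctg & feats$strand == s, , drop = FALSE]
      if (!nrow(sub)) next
      len <- coverage$contigs[[ctg]]
      coding <- logical(len)
      for (i in seq_len(nrow(sub)))
        coding[(sub$start[i] + 1L):sub$end[i]] <- TRUE
      hit <- logical(len)
      for (cond in coverage$conditions)
        hit <- hit | (coverage$depth[[cond]][[s]][[ctg]] >= min_depth)
      covered <- covered + sum(hit & coding)
      total <- total + sum(coding)
    }
  }
  covered / total
}
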