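#' Pipeline configuration
#'
#' Bundles every stage threshold with its default.  The defaults are the
#' printed operating points of the method: novel transcripts need depth >= 5
#' in >= 3 conditions over > 200 bp; operons allow gaps < 150 bp and require
#' profile correlation > 0.6; 5' peaks are paired/assigned within 200 bp,
#' with a 150 bp post-peak exclusion zone, calibration correlation >= 0.6
#' and >= 5 supporting reads; DE calls need adjusted p < 0.01 and
#' |log2FC| > 2; enrichment uses FDR 0.05; hypothetical-protein links need
#' r > 0.9.
#'
#' @param min_depth,min_conditions,min_len novel-transcript rule.
#' @param antisense_overlap fraction of a novel transcript overlapping an
#'   opposite-strand gene for an antisense call.
#' @param max_gap,min_r operon chaining rule.
#' @param link_r hypothetical-protein linking threshold.
#' @param peak_window peak pairing/assignment window (bp).
#' @param exclusion post-peak 5'-bias exclusion (bp).
#' @param coverage_window downstream-coverage window for peak filtering (bp).
#' @param calibration_r minimum usable calibration correlation.
#' @param band_quantiles calibration residual acceptance band.
#' @param min_support minimum 5'-peak read support.
#' @param confirm_tol peak offsets up to this count as confirmed (bp).
#' @param p_adj_cut,lfc_cut,delta_lfc DE calling and rescue rule.
#' @param fdr enrichment FDR.
#' @param dispersion fixed NB dispersion of the exact DE test.
#' @param read_length mean read length for count reconstruction (bp).
#' @param covered_min_depth,coding_min_depth coverage-statistic thresholds.
#' @param seed recorded seed (the pipeline itself is deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_depth = 5, min_conditions = 3, min_len = 201,
                            antisense_overlap = 0.5,
                            max_gap = 149, min_r = 0.6, link_r = 0.9,
                            peak_window = 200, exclusion = 150,
                            coverage_window = 300,
                            calibration_r = 0.6,
                            band_quantiles = c(0.025, 0.975),
                            min_support = 5, confirm_tol = 3,
                            p_adj_cut = 0.01, lfc_cut = 2, delta_lfc = 1.0,
                            fdr = 0.05, dispersion = 0.1, read_length = 76,
                            covered_min_depth = 3, coding_min_depth = 2,
                            seed = 1L) {
  cfg <- as.list(environment())
  num <- vapply(cfg, is.numeric, logical(1))
  if (any(vapply(cfg[num], function(x) any(x < 0), logical(1))))
    stop("pipeline thresholds must be non-negative")
  for (f in c("min_depth", "min_conditions", "min_len", "max_gap",
              "peak_window", "min_support", "read_length"))
    if (cfg[[f]] <= 0) stop(f, " must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full annotation and expression pipeline
#'
#' Executes quantification (RPKM, profile consistency, coverage fractions),
#' 5' analysis when a track is present (peak calling, Passing-Bablok
#' calibration, reliability filtering, start-site calls), structural
#' annotation (novel/antisense transcripts, transcriptional units),
#' differential expression against the reference condition with
#' pathway/TU rescue, COG enrichment, condition clustering and
#' hypothetical-protein linking, then summarises the structural annotation.
#' Without a 5' track the TU caller runs with the internal-peak rule
#' disabled and 5' summary rows are marked not applicable.  All stages are
#' pure functions of the inputs and configuration.
#'
#' @param genome an [annotated_genome()].
#' @param coverage a [coverage_set()].
#' @param track optional pooled [fiveprime_track()].
#' @param config a [pipeline_config()].
#' @param reference reference condition label (default: first condition).
#' @param out_dir optional directory for TSV/GFF3/BED/Newick reports.
#' @return list of class `cyanotx_run` with elements `expression`,
#'   `consistency`, `coverage_stats`, `peaks`, `calibration`, `start_sites`,
#'   `novel`, `tus`, `de`, `enrichment`, `clustering`, `links`, `summary`
#'   and `config`.
#' @export
run_pipeline <- function(genome, coverage, track = NULL,
                         config = pipeline_config(),
                         reference = coverage$conditions[1],
                         out_dir = NULL) {
  cfg <- config
  expr <- run_stage("quantify",
                    rpkm_matrix(genome, coverage, cfg$read_length))
  consistency <- run_stage("quantify",
                           profile_consistency(genome, coverage))
  covstats <- run_stage("quantify", data.frame(
    statistic = c("genome_covered_fraction", "coding_covered_fraction"),
    value = c(genome_covered_fraction(coverage, cfg$covered_min_depth),
              coding_covered_fraction(genome, coverage, cfg$coding_min_depth))))

  peaks <- calibration <- start_sites <- assignments <- NULL
  if (!is.null(track) && nrow(track)) {
    peaks <- run_stage("tss", call_peaks(track, cfg$min_support))
    cal_ids <- run_stage("tss", build_calibration_set(genome, cfg$exclusion))
    calibration <- run_stage("tss",
      calibrate_peaks(genome, coverage, peaks, cal_ids,
                      exclude_bp = cfg$exclusion,
                      max_upstream = cfg$peak_window,
                      min_r = cfg$calibration_r,
                      band_quantiles = cfg$band_quantiles))
    if (calibration$usable) {
      reliable <- run_stage("tss",
        filter_reliable_peaks(peaks, calibration, coverage,
                              min_support = cfg$min_support,
                              exclude_bp = cfg$exclusion,
                              window = cfg$coverage_window))
      assignments <- run_stage("tss",
        assign_peaks(genome, reliable, max_dist = cfg$peak_window,
                     confirm_tol = cfg$confirm_tol))
      start_sites <- assignments$calls
      peaks <- reliable
    } else {
      message("run_pipeline: ", calibration$status,
              "; start-site correction skipped")
    }
  }

  novel <- run_stage("structure",
    find_novel_transcripts(genome, coverage, cfg$min_depth,
                           cfg$min_conditions, cfg$min_len,
                           cfg$antisense_overlap))
  tus <- run_stage("structure",
    find_operons(genome, expr, assignments, cfg$max_gap, cfg$min_r))

  counts <- run_stage("de", gene_counts(genome, coverage, cfg$read_length))
  contrasts <- setdiff(coverage$conditions, reference)
  de <- run_stage("de", do.call(rbind, lapply(contrasts, function(cond) {
    d <- de_test(counts, c(reference, cond), coverage$total_mapped,
                 cfg$dispersion, cfg$p_adj_cut, cfg$lfc_cut)
    augment_de(d, genome, tus, cfg$delta_lfc)
  })))
  enrichment <- run_stage("enrich", do.call(rbind, lapply(contrasts,
    function(cond) enrich_cog(de[de$contrast == paste(cond, "vs", reference), ],
                              genome, cfg$fdr))))
  clustering <- run_stage("cluster", cluster_conditions(expr))
  links <- run_stage("link", link_hypotheticals(expr, genome, cfg$link_r))

  n_genes <- sum(genome$features$ftype == "CDS")
  n_shift <- if (!is.null(start_sites)) sum(start_sites$status == "shifted")
             else NA_integer_
  multi <- tus$tus$n_genes > 1
  tu_has_peak <- if (!is.null(assignments)) {
    peak_genes <- assignments$calls$gene[
      assignments$calls$status %in% c("confirmed", "shifted")]
    vapply(tus$members, function(m) m[1] %in% peak_genes, logical(1))
  } else rep(NA, nrow(tus$tus))
  summary_tab <- data.frame(
    statistic = c("total_genes", "genes_without_conflicts",
                  "genes_with_altered_start", "novel_genes",
                  "antisense_transcripts", "total_tus", "multi_gene_tus",
                  "genes_in_multi_gene_tus", "tus_with_5p_peak",
                  "tus_without_5p_peak"),
    value = c(n_genes, n_genes - if (is.na(n_shift)) 0L else n_shift,
              n_shift, sum(novel$klass == "intergenic"),
              sum(novel$klass == "antisense"), nrow(tus$tus), sum(multi),
              sum(tus$tus$n_genes[multi]),
              if (all(is.na(tu_has_peak))) NA_integer_ else sum(tu_has_peak),
              if (all(is.na(tu_has_peak))) NA_integer_ else sum(!tu_has_peak)))

  run <- structure(list(expression = expr, consistency = consistency,
                        coverage_stats = covstats, peaks = peaks,
                        calibration = calibration, start_sites = start_sites,
                        novel = novel, tus = tus, de = de,
                        enrichment = enrichment, clustering = clustering,
                        links = links, summary = summary_tab, config = cfg),
                   class = "cyanotx_run")
  if (!is.null(out_dir)) write_run(run, genome, out_dir)
  run
}

#' @export
print.cyanotx_run <- function(x, ...) {
  cat("cyanotx pipeline run\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("DE: %d called across %d contrasts; %d enriched categories; %d links\n",
              sum(x$de$called), length(unique(x$de$contrast)),
              if (nrow(x$enrichment)) sum(x$enrichment$significant) else 0L,
              nrow(x$links)))
  invisible(x)
}

write_run <- function(run, genome, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_tsv(cbind(gene = rownames(run$expression),
                  as.data.frame(unclass(run$expression), check.names = FALSE)),
            p("expression.tsv"))
  write_tsv(run$consistency, p("consistency.tsv"))
  write_tsv(run$coverage_stats, p("coverage_stats.tsv"))
  if (!is.null(run$peaks)) {
    det <- attr(run$peaks, "detail") %||% as.data.frame(run$peaks)
    write_tsv(det, p("peaks.tsv"))
  }
  if (!is.null(run$start_sites)) {
    write_tsv(run$start_sites, p("start_sites.tsv"))
    corrected <- apply_start_corrections(genome, run$start_sites)
    write_features_gff3(corrected, path = p("corrected_genes.gff3"))
  }
  if (nrow(run$novel)) {
    nf <- feature_df(run$novel$id, run$novel$contig, run$novel$start,
                     run$novel$end, run$novel$strand,
                     ifelse(run$novel$klass == "antisense", "antisense",
                            "novel"))
    write_features_bed(nf, p("novel.bed"), genome)
    write_features_gff3(genome, nf, p("novel.gff3"))
  }
  write_tsv(run$novel, p("novel.tsv"))
  write_tsv(run$tus$tus, p("tus.tsv"))
  tu_feats <- feature_df(run$tus$tus$tu_id, run$tus$tus$contig,
                         run$tus$tus$start, run$tus$tus$end,
                         run$tus$tus$strand, "TU")
  write_features_bed(tu_feats, p("tus.bed"), genome)
  write_tsv(run$de, p("de.tsv"))
  if (nrow(run$enrichment)) write_tsv(run$enrichment, p("enrichment.tsv"))
  write_dendrogram_newick(run$clustering, p("conditions.nwk"))
  write_tsv(run$links, p("links.tsv"))
  write_tsv(run$summary, p("summary.tsv"))
  yaml::write_yaml(unclass(run$config), p("run_config.yaml"))
  invisible(out_dir)
}
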