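#' Simulation configuration
#'
#' Parameters of the synthetic transcriptome generator.  The defaults emulate
#' a compact cyanobacterial chromosome surveyed under one reference condition
#' plus five stresses sampled at 1 h and 24 h (11 single-library conditions),
#' with a pooled 5'-enriched track whose peak heights scale with downstream
#' coverage.
#'
#' @param seed integer RNG seed; all outputs are reproducible from it.
#' @param contig_length chromosome length in bp.
#' @param n_genes number of annotated CDSs.
#' @param operon_fraction fraction of genes placed in 2-5-gene operons.
#' @param operon_size_range smallest/largest operon size.
#' @param n_novel planted unannotated intergenic transcripts.
#' @param n_antisense planted antisense transcripts (inside genes, opposite
#'   strand).
#' @param n_start_shifts genes whose true TSS is planted downstream of the
#'   annotated start; the first planted offset is always 60 bp, the rest are
#'   drawn from `start_shift_range`.
#' @param start_shift_range offset range in bp.
#' @param n_conditions odd count: 1 reference + stresses x 2 timepoints.
#' @param nb_dispersion negative-binomial dispersion of the per-gene
#'   expression level drawn once around `base_depth` (0 = deterministic).
#'   Conditions share this draw; across-condition variation comes from the
#'   planted condition multipliers, a per-condition sequencing-depth factor
#'   and per-base Poisson counting noise, mirroring a design with a single
#'   library per condition.
#' @param base_depth mean per-base depth of an average gene.
#' @param read_length mean read length (bp) used to convert depth to reads.
#' @param fiveprime_noise_sd log-normal sd of 5' peak height about the
#'   calibration line.
#' @param outlier_peak_fraction fraction of spurious 5' peaks (uncorrelated
#'   with coverage) added to the track.
#' @param peak_scale proportionality constant between mean downstream
#'   coverage and true 5' peak height.
#' @param de_fraction probability that a profile responds strongly
#'   (|log2FC| >= 2, recorded as ground truth) to a given stress.
#' @param de_lfc_range magnitude range of planted strong fold changes.
#' @param mod_fraction probability of a mild (non-DE) response to a stress.
#' @param mod_lfc_range magnitude range of mild responses.
#' @param gene_length_range,operon_gap_range,intergenic_gap_range,novel_length_range
#'   layout draws in bp; intergenic gaps are >= 200 bp so that tandem
#'   non-operon genes never satisfy the operon gap rule, and within-operon
#'   gaps are < 150 bp so planted operons always do.
#' @param novel_base_depth mean plateau depth of planted novel/antisense
#'   transcripts.
#' @param taper_amplitude linear 5'->3' coverage taper (0 disables).
#' @param shape_sd per-gene smooth positional coverage bias (log scale, fixed
#'   across conditions; 0 disables).
#' @param shape_smooth smoothing window (bp) of the positional bias.
#' @param per_base_noise draw per-base depths as Poisson counts (`TRUE`) or
#'   deterministically rounded (`FALSE`).
#' @param sequencing_depth_sd log-normal sd of the per-condition library-size
#'   factor (0 disables).
#' @param cog_fraction fraction of genes given a COG category; genes without
#'   one are treated as hypothetical proteins.
#' @param pathway_fraction fraction of singleton genes given a pathway label
#'   (operon members always share one).
#' @param background_fraction fraction of positions per track receiving 1-3
#'   reads of background noise.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       contig_length = 200000L,
                       n_genes = 150L,
                       operon_fraction = 0.4,
                       operon_size_range = c(2L, 5L),
                       n_novel = 12L,
                       n_antisense = 10L,
                       n_start_shifts = 8L,
                       start_shift_range = c(30L, 120L),
                       n_conditions = 11L,
                       nb_dispersion = 0.2,
                       base_depth = 30,
                       read_length = 76,
                       fiveprime_noise_sd = 0.3,
                       outlier_peak_fraction = 0.1,
                       peak_scale = 2,
                       de_fraction = 0.15,
                       de_lfc_range = c(2, 4.5),
                       mod_fraction = 0.5,
                       mod_lfc_range = c(0.4, 1.5),
                       gene_length_range = c(600L, 1200L),
                       operon_gap_range = c(20L, 140L),
                       intergenic_gap_range = c(200L, 500L),
                       novel_length_range = c(250L, 400L),
                       novel_base_depth = 25,
                       taper_amplitude = 0.15,
                       shape_sd = 0.4,
                       shape_smooth = 50L,
                       per_base_noise = TRUE,
                       sequencing_depth_sd = 0.15,
                       cog_fraction = 0.85,
                       pathway_fraction = 0.6,
                       background_fraction = 0.004) {
  cfg <- as.list(environment())
  stopifnot(cfg$contig_length > 0, cfg$n_genes > 0,
            cfg$operon_fraction >= 0, cfg$operon_fraction <= 1,
            cfg$n_conditions >= 3, cfg$n_conditions %% 2 == 1,
            cfg$nb_dispersion >= 0, cfg$base_depth > 0,
            cfg$fiveprime_noise_sd >= 0, cfg$outlier_peak_fraction >= 0)
  class(cfg) <- "sim_config"
  cfg
}

.cog_letters <- c("C", "E", "F", "G", "H", "I", "J", "K", "L", "M",
                  "N", "O", "P", "Q", "T", "U", "V")

sim_condition_labels <- function(n_conditions) {
  n_stress <- (n_conditions - 1L) %/% 2L
  codes <- if (n_stress <= 5L) c("S", "L", "T", "P", "C")[seq_len(n_stress)]
           else paste0("S", seq_len(n_stress))
  c("Ref", as.vector(t(outer(codes, c("1h", "24h"), paste, sep = "."))))
}

# stress index of each condition label (NA for the reference)
sim_condition_stress <- function(labels) {
  s <- sub("\\.(1h|24h)$", "", labels)
  s[labels == "Ref"] <- NA
  s
}

runif_int <- function(n, range) {
  if (range[1] >= range[2]) rep(as.integer(range[1]), n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

# smooth multiplicative per-gene coverage shape, mean exactly 1
gene_shape <- function(len, taper_amplitude, shape_sd, shape_smooth) {
  shape <- rep(1, len)
  if (taper_amplitude > 0)
    shape <- 1 + taper_amplitude * (1 - 2 * (seq_len(len) - 0.5) / len)
  if (shape_sd > 0) {
    w <- max(3L, min(as.integer(shape_smooth), len))
    z <- as.numeric(stats::filter(rnorm(len), rep(1 / w, w), sides = 2))
    z[is.na(z)] <- 0
    if (sd(z) > 0) z <- z / sd(z)
    shape <- shape * exp(shape_sd * z)
  }
  shape / mean(shape)
}

#' Simulate an annotated genome with coverage, 5' track and ground truth
#'
#' Generates (1) an annotated genome whose CDSs are laid out as singleton
#' genes and 2-5-gene operons, with planted unannotated intergenic and
#' antisense transcripts and planted start-site shifts; (2) stranded per-base
#' coverage for every condition, built from a per-gene negative-binomial
#' expression level shared across conditions, planted per-stress fold
#' changes, a per-condition depth factor, a fixed per-gene positional shape
#' with a mild 5'->3' taper, and per-base Poisson noise; (3) a pooled 5' peak
#' track whose peak heights are proportional to mean downstream coverage with
#' log-normal noise, plus spurious outlier peaks; and (4) truth tables for
#' recovery scoring.
#'
#' Planted novel/antisense transcripts are guaranteed to satisfy the
#' detection rule (depth >= 5 at every base in >= 3 conditions, length
#' > 200 bp): in their three strongest conditions the plateau is floored at
#' depth 5.
#'
#' @param config a [sim_config()].
#' @return list of class `cyanotx_sim` with elements `genome`
#'   ([annotated_genome()]), `coverage` ([coverage_set()]), `track`
#'   ([fiveprime_track()]), `truth` (see Details) and `config`.
#'
#' @details `truth` contains `operons` (list of gene-id vectors in
#'   transcription order), `novel` and `antisense` feature tables,
#'   `start_shifts` (named bp offsets), `de_genes` (gene, condition, planted
#'   log2FC for |log2FC| >= 2), `true_lfc` (full gene x condition matrix of
#'   planted log2 multipliers) and `gene_levels` (per-gene NB expression
#'   draws).
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  L <- as.integer(cfg$contig_length)
  ctg <- "chr"
  conditions <- sim_condition_labels(cfg$n_conditions)
  stress_of <- sim_condition_stress(conditions)
  stresses <- unique(stress_of[!is.na(stress_of)])

  ## ---- layout -------------------------------------------------------------
  n_op_genes <- round(cfg$operon_fraction * cfg$n_genes)
  op_sizes <- integer(0)
  rem <- n_op_genes
  smin <- cfg$operon_size_range[1]; smax <- cfg$operon_size_range[2]
  while (rem >= smin) {
    s <- sample(seq.int(smin, min(smax, rem)), 1L)
    if (rem - s > 0 && rem - s < smin) s <- rem  # avoid stranding < smin genes
    if (s > min(smax, rem)) s <- rem
    op_sizes <- c(op_sizes, s)
    rem <- rem - s
  }
  n_single <- cfg$n_genes - sum(op_sizes)
  blocks <- c(lapply(op_sizes, function(s) list(type = "operon", size = s)),
              replicate(n_single, list(type = "gene", size = 1L),
                        simplify = FALSE),
              replicate(cfg$n_novel, list(type = "novel", size = 1L),
                        simplify = FALSE))
  blocks <- blocks[sample.int(length(blocks))]

  rows <- list()
  pos <- runif_int(1L, cfg$intergenic_gap_range)
  gi <- 0L; ni <- 0L; oi <- 0L
  operon_members <- list()
  for (b in blocks) {
    strand <- sample(c("+", "-"), 1L)
    if (b$type == "novel") {
      ni <- ni + 1L
      len <- runif_int(1L, cfg$novel_length_range)
      rows[[length(rows) + 1L]] <-
        data.frame(id = sprintf("novel_%02d", ni), kind = "novel",
                   start = pos, end = pos + len, strand = strand,
                   operon = NA_integer_)
      pos <- pos + len
    } else {
      op <- if (b$type == "operon") { oi <- oi + 1L; oi } else NA_integer_
      ids <- character(b$size)
      for (k in seq_len(b$size)) {
        gi <- gi + 1L
        len <- runif_int(1L, cfg$gene_length_range)
        id <- sprintf("gene_%04d", gi)
        ids[k] <- id
        rows[[length(rows) + 1L]] <-
          data.frame(id = id, kind = "gene", start = pos, end = pos + len,
                     strand = strand, operon = op)
        pos <- pos + len
        if (k < b$size) pos <- pos + runif_int(1L, cfg$operon_gap_range)
      }
      if (b$type == "operon")
        operon_members[[oi]] <- if (strand == "+") ids else rev(ids)
    }
    pos <- pos + runif_int(1L, cfg$intergenic_gap_range)
  }
  if (pos > L)
    stop("infeasible packing: features need ", pos,
         " bp but contig_length is ", L, "; increase contig_length")
  layout <- do.call(rbind, rows)

  genes <- layout[layout$kind == "gene", , drop = FALSE]
  novel <- layout[layout$kind == "novel", , drop = FALSE]

  ## ---- antisense ----------------------------------------------------------
  as_rows <- list()
  if (cfg$n_antisense > 0) {
    host_pool <- genes$id[genes$end - genes$start >=
                            cfg$novel_length_range[1] + 40L]
    if (length(host_pool) < cfg$n_antisense)
      stop("infeasible packing: not enough genes to host antisense features")
    hosts <- sample(host_pool, cfg$n_antisense)
    for (k in seq_along(hosts)) {
      g <- genes[genes$id == hosts[k], ]
      maxlen <- min(cfg$novel_length_range[2], g$end - g$start - 40L)
      len <- runif_int(1L, c(cfg$novel_length_range[1], maxlen))
      off <- runif_int(1L, c(20L, g$end - g$start - len - 20L))
      as_rows[[k]] <- data.frame(id = sprintf("as_%02d", k), kind = "antisense",
                                 start = g$start + off,
                                 end = g$start + off + len,
                                 strand = if (g$strand == "+") "-" else "+",
                                 operon = NA_integer_,
                                 opposite_gene = g$id)
    }
  }
  antisense <- if (length(as_rows)) do.call(rbind, as_rows) else
    data.frame(id = character(0), kind = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               operon = integer(0), opposite_gene = character(0))

  ## ---- functional labels --------------------------------------------------
  n_g <- nrow(genes)
  genes$cog <- ifelse(stats::runif(n_g) < cfg$cog_fraction,
                      sample(.cog_letters, n_g, replace = TRUE),
                      NA_character_)
  genes$pathway <- NA_character_
  if (length(operon_members)) {
    op_pw <- sprintf("pw_op%02d", seq_along(operon_members))
    for (i in seq_along(operon_members))
      genes$pathway[genes$id %in% operon_members[[i]]] <- op_pw[i]
  }
  singles <- is.na(genes$operon)
  give_pw <- singles & stats::runif(n_g) < cfg$pathway_fraction
  genes$pathway[give_pw] <- sample(sprintf("pw_%02d", 1:25), sum(give_pw),
                                   replace = TRUE)

  ## ---- expression programme -----------------------------------------------
  # one profile per operon / singleton gene / novel / antisense feature
  genes$profile <- ifelse(is.na(genes$operon), paste0("sg_", genes$id),
                          paste0("op_", genes$operon))
  profiles <- unique(genes$profile)
  feat_profiles <- c(novel$id, antisense$id)
  lfc <- matrix(0, nrow = length(profiles) + length(feat_profiles),
                ncol = length(stresses),
                dimnames = list(c(profiles, feat_profiles), stresses))
  for (p in rownames(lfc)) {
    is_cds_profile <- p %in% profiles
    for (s in stresses) {
      u <- stats::runif(1)
      sign <- sample(c(-1, 1), 1L)
      if (is_cds_profile && u < cfg$de_fraction) {
        lfc[p, s] <- sign * stats::runif(1, cfg$de_lfc_range[1],
                                         cfg$de_lfc_range[2])
      } else if (u < cfg$de_fraction + cfg$mod_fraction) {
        lfc[p, s] <- sign * stats::runif(1, cfg$mod_lfc_range[1],
                                         cfg$mod_lfc_range[2])
      }
    }
  }

  # per-gene expression level: a single NB draw shared by all conditions
  draw_level <- function(n, mu) {
    if (cfg$nb_dispersion > 0)
      rnbinom(n, size = 1 / cfg$nb_dispersion, mu = mu)
    else rep(mu, n)
  }
  genes$level <- draw_level(n_g, cfg$base_depth)
  novel$level <- pmax(18, round(exp(rnorm(nrow(novel),
                                          log(cfg$novel_base_depth), 0.3))))
  antisense$level <- pmax(18, round(exp(rnorm(nrow(antisense),
                                              log(cfg$novel_base_depth), 0.3))))

  depth_factor <- if (cfg$sequencing_depth_sd > 0)
    exp(rnorm(length(conditions), 0, cfg$sequencing_depth_sd)) else
      rep(1, length(conditions))
  names(depth_factor) <- conditions

  cond_mult <- function(profile) {  # per-condition multiplier 2^lfc
    out <- rep(1, length(conditions)); names(out) <- conditions
    st <- stress_of[match(conditions, conditions)]
    has <- !is.na(st)
    out[has] <- 2^lfc[profile, st[has]]
    out
  }

  ## ---- start shifts -------------------------------------------------------
  shift_pool <- genes$id[is.na(genes$operon) & genes$level >= 15]
  if (length(shift_pool) < cfg$n_start_shifts)
    stop("not enough well-expressed singleton genes to plant start shifts")
  shift_ids <- sample(shift_pool, cfg$n_start_shifts)
  offsets <- integer(0)
  if (cfg$n_start_shifts > 0) {
    offsets <- c(60L, runif_int(cfg$n_start_shifts - 1L,
                                cfg$start_shift_range))[seq_len(cfg$n_start_shifts)]
    names(offsets) <- shift_ids
  }
  genes$tss_offset <- 0L
  genes$tss_offset[match(shift_ids, genes$id)] <- offsets

  # transcribed span (annotation keeps the original start)
  genes$tx_start <- ifelse(genes$strand == "+", genes$start + genes$tss_offset,
                           genes$start)
  genes$tx_end <- ifelse(genes$strand == "+", genes$end,
                         genes$end - genes$tss_offset)

  ## ---- coverage -----------------------------------------------------------
  depth <- lapply(conditions, function(cond)
    list(`+` = list(chr = numeric(L)), `-` = list(chr = numeric(L))))
  names(depth) <- conditions

  add_block <- function(cond, strand, from, to, level, shape = NULL) {
    # from/to: 0-based half-open; returns nothing, mutates `depth` in parent
    idx <- (from + 1L):to
    lam <- level * depth_factor[[cond]]
    lam <- if (is.null(shape)) rep(lam, length(idx)) else lam * shape
    v <- if (cfg$per_base_noise) rpois(length(idx), lam) else round(lam)
    depth[[cond]][[strand]][[ctg]][idx] <<- depth[[cond]][[strand]][[ctg]][idx] + v
  }

  gene_shapes <- lapply(seq_len(n_g), function(i)
    gene_shape(genes$tx_end[i] - genes$tx_start[i], cfg$taper_amplitude,
               cfg$shape_sd, cfg$shape_smooth))
  feat_tabs <- list(novel = novel, antisense = antisense)
  feat_shapes <- lapply(feat_tabs, function(tab)
    lapply(seq_len(nrow(tab)), function(i)
      gene_shape(tab$end[i] - tab$start[i], 0, cfg$shape_sd, cfg$shape_smooth)))

  for (cond in conditions) {
    for (i in seq_len(n_g)) {
      m <- cond_mult(genes$profile[i])[[cond]]
      add_block(cond, genes$strand[i], genes$tx_start[i], genes$tx_end[i],
                genes$level[i] * m, gene_shapes[[i]])
    }
    # read-through between operon members: intergenic coverage inside operons
    for (op in seq_along(operon_members)) {
      mem <- genes[!is.na(genes$operon) & genes$operon == op, , drop = FALSE]
      mem <- mem[order(mem$start), , drop = FALSE]
      m <- cond_mult(mem$profile[1])[[cond]]
      if (nrow(mem) > 1L)
        for (k in seq_len(nrow(mem) - 1L))
          if (mem$end[k] < mem$start[k + 1L])
            add_block(cond, mem$strand[1], mem$end[k], mem$start[k + 1L],
                      0.4 * min(mem$level[k], mem$level[k + 1L]) * m)
    }
  }

  # novel / antisense plateaus, floored at depth 5 in their 3 strongest
  # conditions so the planted detection rule holds by construction
  for (kind in names(feat_tabs)) {
    tab <- feat_tabs[[kind]]
    for (i in seq_len(nrow(tab))) {
      mults <- vapply(conditions, function(cond)
        cond_mult(tab$id[i])[[cond]] * depth_factor[[cond]], numeric(1))
      top3 <- names(sort(mults, decreasing = TRUE))[1:3]
      for (cond in conditions) {
        add_block(cond, tab$strand[i], tab$start[i], tab$end[i],
                  tab$level[i] * cond_mult(tab$id[i])[[cond]],
                  feat_shapes[[kind]][[i]])
        if (cond %in% top3) {
          idx <- (tab$start[i] + 1L):tab$end[i]
          depth[[cond]][[tab$strand[i]]][[ctg]][idx] <-
            pmax(depth[[cond]][[tab$strand[i]]][[ctg]][idx], 5)
        }
      }
    }
  }

  # sparse low-level background (never reaches the depth-5 detection floor)
  if (cfg$background_fraction > 0) {
    n_bg <- round(cfg$background_fraction * L)
    for (cond in conditions) for (s in c("+", "-")) {
      at <- sample.int(L, n_bg)
      depth[[cond]][[s]][[ctg]][at] <- depth[[cond]][[s]][[ctg]][at] +
        pmin(3, 1 + rpois(n_bg, 0.5))
    }
  }
  for (cond in conditions) for (s in c("+", "-"))
    depth[[cond]][[s]][[ctg]] <- as.integer(depth[[cond]][[s]][[ctg]])

  total_mapped <- vapply(conditions, function(cond)
    max(1, round((sum(depth[[cond]][["+"]][[ctg]]) +
                    sum(depth[[cond]][["-"]][[ctg]])) / cfg$read_length)),
    numeric(1))

  ## ---- 5' track -----------------------------------------------------------
  pooled_mean <- function(strand, from, to) {
    v <- 0
    for (cond in conditions) v <- v + mean(depth[[cond]][[strand]][[ctg]][(from + 1L):to])
    v / length(conditions)
  }
  tss_rows <- list()
  add_tss <- function(pos, strand, from, to) {
    m <- pooled_mean(strand, from, to)
    supp <- max(1, round(cfg$peak_scale * m *
                           exp(rnorm(1, 0, cfg$fiveprime_noise_sd))))
    tss_rows[[length(tss_rows) + 1L]] <<-
      data.frame(contig = ctg, pos = pos, strand = strand, support = supp)
  }
  leader_of <- vapply(operon_members, `[`, character(1), 1)
  for (i in seq_len(n_g)) {
    g <- genes[i, ]
    is_leader <- is.na(g$operon) || g$id %in% leader_of
    if (!is_leader) next
    p <- if (g$strand == "+") g$tx_start else g$tx_end - 1L
    add_tss(p, g$strand, g$tx_start, g$tx_end)
  }
  for (kind in names(feat_tabs)) {
    tab <- feat_tabs[[kind]]
    for (i in seq_len(nrow(tab))) {
      p <- if (tab$strand[i] == "+") tab$start[i] else tab$end[i] - 1L
      add_tss(p, tab$strand[i], tab$start[i], tab$end[i])
    }
  }
  track <- do.call(rbind, tss_rows)
  n_out <- round(cfg$outlier_peak_fraction * nrow(track))
  if (n_out > 0) {
    out <- data.frame(contig = ctg,
                      pos = sample.int(L, n_out) - 1L,
                      strand = sample(c("+", "-"), n_out, replace = TRUE),
                      support = pmax(1, round(exp(rnorm(n_out,
                                                        log(max(5, median(track$support))),
                                                        1)))))
    track <- rbind(track, out)
    track <- track[!duplicated(track[, c("contig", "pos", "strand")]), ,
                   drop = FALSE]
  }

  ## ---- assemble -----------------------------------------------------------
  feats <- feature_df(genes$id, ctg, genes$start, genes$end, genes$strand,
                      "CDS", genes$cog, genes$pathway)
  genome <- annotated_genome(c(chr = L), feats)
  coverage <- coverage_set(conditions, c(chr = L), depth, total_mapped)
  track <- fiveprime_track(track, c(chr = L))

  true_lfc <- matrix(0, n_g, length(conditions),
                     dimnames = list(genes$id, conditions))
  for (j in seq_along(conditions)) {
    s <- stress_of[j]
    if (!is.na(s)) true_lfc[, j] <- lfc[genes$profile, s]
  }
  de_idx <- which(abs(true_lfc) >= 2, arr.ind = TRUE)
  de_genes <- data.frame(gene = rownames(true_lfc)[de_idx[, 1]],
                         condition = colnames(true_lfc)[de_idx[, 2]],
                         log2fc = true_lfc[de_idx],
                         stringsAsFactors = FALSE)
  de_genes <- de_genes[order(de_genes$gene, de_genes$condition), , drop = FALSE]
  rownames(de_genes) <- NULL

  truth <- list(
    operons = operon_members,
    novel = feature_df(novel$id, ctg, novel$start, novel$end, novel$strand,
                       "novel"),
    antisense = cbind(feature_df(antisense$id, ctg, antisense$start,
                                 antisense$end, antisense$strand, "antisense"),
                      opposite_gene = antisense$opposite_gene),
    start_shifts = offsets,
    de_genes = de_genes,
    true_lfc = true_lfc,
    gene_levels = setNames(genes$level, genes$id),
    profiles = setNames(genes$profile, genes$id),
    depth_factor = depth_factor)

  structure(list(genome = genome, coverage = coverage, track = track,
                 truth = truth, config = cfg),
            class = "cyanotx_sim")
}

#' @export
print.cyanotx_sim <- function(x, ...) {
  cat("Synthetic transcriptome (seed ", x$config$seed, "):\n", sep = "")
  cat("  ", nrow(x$genome$features), " genes on ", sum(x$genome$contigs),
      " bp; ", length(x$truth$operons), " operons; ",
      nrow(x$truth$novel), " novel; ", nrow(x$truth$antisense),
      " antisense; ", length(x$truth$start_shifts), " start shifts\n", sep = "")
  cat("  ", length(x$coverage$conditions), " conditions; ",
      nrow(x$track), " 5' peaks\n", sep = "")
  invisible(x)
}

#' Serialize a simulated dataset to a fixture directory
#'
#' Writes `genome.gff3`, per-condition stranded bedGraphs plus `totals.tsv`
#' under `coverage/`, the pooled 5' table `fiveprime.tsv`, truth tables under
#' `truth/` and the configuration as `config.yaml`.  Regenerating with the
#' same seed overwrites to identical bytes.
#'
#' @param sim result of [simulate_transcriptome()].
#' @param dir output directory.
#' @return named list of paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(dir, "genome.gff3")
  write_features_gff3(sim$genome, path = gff)
  cov <- write_coverage_bedgraph(sim$coverage, file.path(dir, "coverage"))
  fp <- write_fiveprime_table(sim$track, file.path(dir, "fiveprime.tsv"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  op <- data.frame(
    operon = rep(seq_along(sim$truth$operons),
                 lengths(sim$truth$operons)),
    position = unlist(lapply(lengths(sim$truth$operons), seq_len)),
    gene = unlist(sim$truth$operons))
  write_tsv(op, file.path(tdir, "operons.tsv"))
  write_tsv(sim$truth$novel, file.path(tdir, "novel.tsv"))
  write_tsv(sim$truth$antisense, file.path(tdir, "antisense.tsv"))
  write_tsv(data.frame(gene = names(sim$truth$start_shifts),
                       offset = unname(sim$truth$start_shifts)),
            file.path(tdir, "start_shifts.tsv"))
  write_tsv(sim$truth$de_genes, file.path(tdir, "de_genes.tsv"))
  write_tsv(cbind(gene = rownames(sim$truth$true_lfc),
                  as.data.frame(sim$truth$true_lfc, check.names = FALSE)),
            file.path(tdir, "true_lfc.tsv"))
  cfg <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(sim$config), cfg)
  invisible(list(genome = gff, coverage = cov, fiveprime = fp,
                 truth = tdir, config = cfg))
}

#' Read a fixture directory back into memory
#'
#' Inverse of [write_fixture()] for the genome, coverage and 5' track (truth
#' tables are read as plain data frames).
#'
#' @param dir fixture directory.
#' @return list with `genome`, `coverage`, `track`, `config`.
#' @export
read_fixture <- function(dir) {
  genome <- read_genome_gff3(file.path(dir, "genome.gff3"))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  tot <- read.table(file.path(dir, "coverage", "totals.tsv"), header = TRUE,
                    sep = "\t")
  conds <- as.character(tot$condition)
  paths <- lapply(conds, function(cond) {
    base <- gsub("[^A-Za-z0-9._-]", "_", cond)
    list(`+` = file.path(dir, "coverage", paste0(base, "_plus.bedGraph")),
         `-` = file.path(dir, "coverage", paste0(base, "_minus.bedGraph")))
  })
  names(paths) <- conds
  coverage <- read_coverage_bedgraph(paths,
                                     setNames(tot$total_mapped, conds),
                                     genome$contigs)
  track <- read_fiveprime_table(file.path(dir, "fiveprime.tsv"),
                                genome$contigs)
  list(genome = genome, coverage = coverage, track = track, config = cfg)
}
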