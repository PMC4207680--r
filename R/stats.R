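#' Exact negative-binomial differential expression test
#'
#' Two-condition, single-library-per-condition exact test at a fixed
#' dispersion.  Counts are scaled to the geometric-mean library size and the
#' test conditions on their sum: under the null of equal means the scaled
#' count of the first condition given the sum `s` has the distribution
#' proportional to `f(a) f(s - a)` with `f` the NB(mu = s/2,
#' size = 1/dispersion) pmf (the binomial(s, 1/2) conditional in the Poisson
#' limit `dispersion = 0`); the two-sided p-value sums the probabilities of
#' all splits no more probable than the observed one.  Library-size-aware
#' log2 fold changes use a pseudocount of 0.5 per condition.  Replicate-based
#' dispersion estimation is undefined with one library per condition, so the
#' dispersion is a fixed, configurable parameter.
#'
#' @param counts numeric matrix genes x conditions of (reconstructed) read
#'   counts, e.g. from [gene_counts()].
#' @param contrast character vector `c(reference, treatment)` naming two
#'   columns; fold changes are treatment over reference.
#' @param lib_sizes named per-condition library sizes (default: the coverage
#'   set's `total_mapped`, falling back to column sums).
#' @param dispersion fixed NB dispersion (default 0.1; 0 gives the exact
#'   Poisson/binomial-conditional test).
#' @param p_cut,lfc_cut calling thresholds: `called` requires adjusted
#'   p < `p_cut` (BH across genes) and |log2FC| > `lfc_cut`.
#' @return data.frame with one row per gene: `gene`, `contrast`, `log2fc`,
#'   `p`, `p_adj`, `called`, `rescue_reason` (all `"none"`; see
#'   [augment_de()]).
#' @export
de_test <- function(counts, contrast, lib_sizes = colSums(counts),
                    dispersion = 0.1, p_cut = 0.01, lfc_cut = 2) {
  stopifnot(length(contrast) == 2L, all(contrast %in% colnames(counts)),
            dispersion >= 0)
  n_ref <- as.numeric(lib_sizes[[contrast[1]]])
  n_trt <- as.numeric(lib_sizes[[contrast[2]]])
  if (is.na(n_ref) || is.na(n_trt) || n_ref <= 0 || n_trt <= 0)
    stop("library sizes must be positive")
  n_star <- sqrt(n_ref * n_trt)
  y_ref <- round(counts[, contrast[1]] * n_star / n_ref)
  y_trt <- round(counts[, contrast[2]] * n_star / n_trt)
  p <- vapply(seq_along(y_ref), function(g)
    nb_exact_p(y_ref[g], y_trt[g], dispersion), numeric(1))
  lfc <- log2((y_trt + 0.5) / (y_ref + 0.5))
  lfc[y_ref == 0 & y_trt == 0] <- 0
  p_adj <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(counts),
             contrast = paste(contrast[2], "vs", contrast[1]),
             log2fc = lfc, p = p, p_adj = p_adj,
             called = p_adj < p_cut & abs(lfc) > lfc_cut,
             rescue_reason = "none", stringsAsFactors = FALSE,
             row.names = NULL)
}

# two-sided Fisher exact p for the 2x2 table rbind(c(a, b), c(c_, d))
fisher2p <- function(a, b, c_, d) {
  fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
}

# two-sided exact conditional NB p-value for one gene
nb_exact_p <- function(y1, y2, dispersion) {
  s <- y1 + y2
  if (s == 0) return(1)
  a <- 0:s
  if (dispersion == 0) {
    pr <- dbinom(a, s, 0.5)
  } else {
    f <- dnbinom(a, size = 1 / dispersion, mu = s / 2)
    pr <- f * rev(f)
    pr <- pr / sum(pr)
  }
  obs <- pr[y1 + 1L]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Rescue uncalled genes via shared pathway or transcriptional unit
#'
#' After [de_test()], an uncalled gene becomes called when it shares a
#' pathway with a called gene and its log2 fold change has the same sign and
#' differs by at most `delta_lfc` (`rescue_reason = "pathway"`), or when it
#' belongs to the same transcriptional unit as a called gene
#' (`rescue_reason = "tu"`).  A single pass from the originally called genes
#' is performed; rescued genes do not themselves rescue.
#'
#' @param de result of [de_test()].
#' @param genome an [annotated_genome()] carrying pathway labels.
#' @param tus optional `tu_set` from [find_operons()].
#' @param delta_lfc largest "similar" fold-change difference (default 1.0).
#' @return `de` with updated `called` and `rescue_reason`.
#' @export
augment_de <- function(de, genome, tus = NULL, delta_lfc = 1.0) {
  seeds <- de[de$called, , drop = FALSE]
  if (!nrow(seeds)) return(de)
  feats <- genome$features
  pw <- setNames(feats$pathway, feats$id)
  tu_of <- character(0)
  if (!is.null(tus))
    tu_of <- setNames(rep(names(tus$members), lengths(tus$members)),
                      unlist(tus$members))
  for (i in which(!de$called)) {
    g <- de$gene[i]
    if (!is.na(pw[g]) && any(!is.na(pw[seeds$gene]) & pw[seeds$gene] == pw[g] &
                             sign(seeds$log2fc) == sign(de$log2fc[i]) &
                             sign(de$log2fc[i]) != 0 &
                             abs(seeds$log2fc - de$log2fc[i]) <= delta_lfc)) {
      de$called[i] <- TRUE; de$rescue_reason[i] <- "pathway"
    } else if (length(tu_of) && !is.na(tu_of[g]) &&
               tu_of[g] %in% tu_of[seeds$gene]) {
      de$called[i] <- TRUE; de$rescue_reason[i] <- "tu"
    }
  }
  de
}

#' COG gene-set enrichment of differentially expressed genes
#'
#' For each COG category and direction, a two-sided Fisher's exact test on
#' the 2x2 table {in category?} x {called in that direction?} over the gene
#' universe, with Benjamini-Hochberg adjustment across categories within
#' each direction; significance at `fdr`.  Genes may carry several
#' comma-separated categories.
#'
#' @param de (augmented) result of [de_test()].
#' @param genome an [annotated_genome()] carrying COG labels.
#' @param fdr false-discovery-rate threshold (default 0.05).
#' @return data.frame: `category`, `contrast`, `direction`, the 2x2 counts
#'   (`called_in`, `called_out`, `uncalled_in`, `uncalled_out`),
#'   `odds_ratio`, `p`, `p_adj`, `significant`.
#' @export
enrich_cog <- function(de, genome, fdr = 0.05) {
  feats <- genome$features
  cog_of <- strsplit(setNames(feats$cog, feats$id)[de$gene], ",")
  universe <- de$gene
  cats <- sort(unique(unlist(cog_of[!is.na(cog_of)])))
  if (!length(cats)) {
    message("enrich_cog: no COG categories in universe; nothing to test")
    return(data.frame())
  }
  out <- list()
  for (direction in c("up", "down")) {
    called <- de$called & (if (direction == "up") de$log2fc > 0
                           else de$log2fc < 0)
    rows <- lapply(cats, function(cat) {
      in_cat <- vapply(cog_of, function(x) !all(is.na(x)) && cat %in% x,
                       logical(1))
      a <- sum(called & in_cat); b <- sum(called & !in_cat)
      c_ <- sum(!called & in_cat); d <- sum(!called & !in_cat)
      p <- fisher2p(a, b, c_, d)
      data.frame(category = cat, contrast = de$contrast[1],
                 direction = direction, called_in = a, called_out = b,
                 uncalled_in = c_, uncalled_out = d,
                 odds_ratio = (a * d) / (b * c_), p = p,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$p_adj <- p.adjust(tab$p, method = "BH")
    tab$significant <- tab$p_adj < fdr
    out[[direction]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hierarchical clustering of conditions
#'
#' Agglomerative clustering of condition columns with distance
#' `1 - Pearson r` and complete linkage.  Ties are broken deterministically
#' by the input column order.
#'
#' @param expression RPKM matrix (genes x conditions).
#' @return list of class `condition_clustering` with the `hclust` object,
#'   the distance matrix and a per-step merge table (`height`, `members`).
#' @export
cluster_conditions <- function(expression) {
  if (ncol(expression) < 3L) stop("clustering needs >= 3 conditions")
  sds <- apply(expression, 2, sd)
  if (any(sds == 0))
    stop("constant expression column(s): ",
         paste(colnames(expression)[sds == 0], collapse = ", "))
  d <- as.dist(1 - cor(expression))
  hc <- hclust(d, method = "complete")
  members <- vector("list", length(hc$height))
  grab <- function(k) if (k < 0) hc$labels[-k] else members[[k]]
  for (step in seq_along(hc$height))
    members[[step]] <- sort(c(grab(hc$merge[step, 1]),
                              grab(hc$merge[step, 2])))
  merges <- data.frame(step = seq_along(hc$height), height = hc$height,
                       members = vapply(members, paste, character(1),
                                        collapse = ","))
  structure(list(hclust = hc, dist = d, merges = merges),
            class = "condition_clustering")
}

#' @export
print.condition_clustering <- function(x, ...) {
  cat("Condition clustering (1 - Pearson, complete linkage):\n")
  print(x$merges)
  invisible(x)
}

#' Write a condition dendrogram as Newick
#'
#' @param clustering result of [cluster_conditions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}

#' Link hypothetical proteins to annotated genes by co-expression
#'
#' Genes without a COG assignment are treated as function-unknown
#' (hypothetical).  For each hypothetical gene, every COG-annotated gene
#' whose RPKM condition profile has Pearson correlation exceeding `min_r` is
#' reported, sorted by decreasing correlation.
#'
#' @param expression RPKM matrix (genes x conditions).
#' @param genome an [annotated_genome()] carrying COG labels.
#' @param min_r correlation that must be exceeded (default 0.9).
#' @return data.frame: `hypothetical`, `annotated`, `cog`, `r`.
#' @export
link_hypotheticals <- function(expression, genome, min_r = 0.9) {
  feats <- genome$features[genome$features$ftype == "CDS", , drop = FALSE]
  cogs <- setNames(feats$cog, feats$id)
  genes <- intersect(rownames(expression), feats$id)
  hyp <- genes[is.na(cogs[genes])]
  known <- genes[!is.na(cogs[genes])]
  empty <- data.frame(hypothetical = character(0), annotated = character(0),
                      cog = character(0), r = numeric(0))
  if (!length(hyp) || !length(known)) return(empty)
  r <- suppressWarnings(cor(t(expression[hyp, , drop = FALSE]),
                            t(expression[known, , drop = FALSE])))
  rows <- list()
  for (h in hyp) {
    hit <- which(exceeds(r[h, ], min_r))
    if (!length(hit)) next
    ord <- hit[order(r[h, hit], decreasing = TRUE)]
    rows[[h]] <- data.frame(hypothetical = h, annotated = known[ord],
                            cog = unname(cogs[known[ord]]),
                            r = unname(r[h, ord]), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  out
}
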