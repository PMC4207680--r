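#' Discover novel intergenic and antisense transcripts from coverage
#'
#' Positions not overlapped by a same-strand annotated feature are scanned
#' per strand.  A reported transcript is a maximal interval over which at
#' least `min_conditions` conditions hold depth >= `min_depth` at every base,
#' with length > 200 bp (`min_len = 201`).  A 1-base dropout in a condition
#' ends that condition's run; `smooth` > 0 first closes per-condition
#' dropouts up to that many bases.  Intervals overlapping an opposite-strand
#' feature by at least `antisense_overlap` of their own length are classed
#' `antisense` (with the opposite gene recorded), the rest `intergenic`.
#'
#' @param genome an [annotated_genome()].
#' @param coverage a [coverage_set()].
#' @param min_depth per-base depth threshold (default 5).
#' @param min_conditions conditions that must hold it (default 3).
#' @param min_len minimum transcript length in bp (default 201, i.e.
#'   strictly greater than 200 bp).
#' @param antisense_overlap fraction of the transcript overlapped by an
#'   opposite-strand feature for an antisense call (default 0.5).
#' @param smooth close per-condition depth dropouts up to this many bp
#'   (default 0: a single-base dropout splits the run).
#' @return data.frame of novel transcripts: `id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `klass`, `length`,
#'   `n_supporting_conditions`, `max_depth`, `opposite_gene`.
#' @export
find_novel_transcripts <- function(genome, coverage, min_depth = 5,
                                   min_conditions = 3, min_len = 201,
                                   antisense_overlap = 0.5, smooth = 0) {
  conds <- coverage$conditions
  k <- min_conditions
  out <- list()
  nid <- 0L
  for (ctg in names(genome$contigs)) {
    len <- genome$contigs[[ctg]]
    for (s in c("+", "-")) {
      feats_s <- genome$features[genome$features$contig == ctg &
                                   genome$features$strand == s, , drop = FALSE]
      anti <- genome$features[genome$features$contig == ctg &
                                genome$features$strand != s, , drop = FALSE]
      mask <- rep(TRUE, len)
      for (i in seq_len(nrow(feats_s)))
        mask[(feats_s$start[i] + 1L):feats_s$end[i]] <- FALSE
      okmat <- matrix(FALSE, len, length(conds))
      for (j in seq_along(conds)) {
        ok <- coverage$depth[[conds[j]]][[s]][[ctg]] >= min_depth
        if (smooth > 0) ok <- close_gaps(ok, smooth)
        okmat[, j] <- ok & mask
      }
      nfmat <- apply(okmat, 2, function(ok) {
        v <- seq_len(len); v[ok] <- len + 1L
        rev(cummin(rev(v)))          # first failing base at or after i
      })
      nok <- rowSums(okmat)
      cand <- nok >= k
      prev_cand <- c(FALSE, cand[-len])
      trans <- matrix(FALSE, len, length(conds))
      trans[1, ] <- okmat[1, ]
      trans[-1, ] <- okmat[-1, , drop = FALSE] & !okmat[-len, , drop = FALSE]
      checkpoints <- which(cand & (!prev_cand | rowSums(trans) > 0))
      last_end <- 0L
      for (i in checkpoints) {
        ends <- nfmat[i, ]
        J <- sort(ends, decreasing = TRUE)[k]   # k-th largest failure point
        if (J - i < min_len || J <= last_end) next
        last_end <- J
        nid <- nid + 1L
        start0 <- i - 1L; end0 <- J - 1L
        tlen <- end0 - start0
        supp <- sum(ends >= J)
        maxd <- 0L
        for (cond in conds)
          maxd <- max(maxd, max(coverage$depth[[cond]][[s]][[ctg]][i:(J - 1L)]))
        opp_gene <- NA_character_; klass <- "intergenic"
        if (nrow(anti)) {
          ovl <- pmin(anti$end, end0) - pmax(anti$start, start0)
          if (any(ovl > 0) && max(ovl) >= antisense_overlap * tlen - .thr_eps) {
            klass <- "antisense"
            opp_gene <- anti$id[which.max(ovl)]
          }
        }
        out[[length(out) + 1L]] <-
          data.frame(id = sprintf("novel_%03d", nid), contig = ctg,
                     start = start0, end = end0, strand = s, klass = klass,
                     length = tlen, n_supporting_conditions = supp,
                     max_depth = maxd, opposite_gene = opp_gene,
                     stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(id = character(0), contig = character(0), start = integer(0),
               end = integer(0), strand = character(0), klass = character(0),
               length = integer(0), n_supporting_conditions = integer(0),
               max_depth = integer(0), opposite_gene = character(0),
               stringsAsFactors = FALSE)
  res <- res[order(res$contig, res$start, res$id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# close FALSE gaps of length <= smooth between TRUE runs
close_gaps <- function(ok, smooth) {
  r <- rle(ok)
  n <- length(r$values)
  fill <- !r$values & r$lengths <= smooth &
    seq_len(n) > 1L & seq_len(n) < n
  r$values[fill] <- TRUE
  inverse.rle(r)
}

#' Infer transcriptional units (operons) from gaps, co-expression and 5' peaks
#'
#' Same-strand tandem CDSs are chained left-to-right (genomically); a gene is
#' chained to the next when the intergenic gap is at most `max_gap` bp and
#' the Pearson correlation of the two genes' RPKM condition profiles exceeds
#' `min_r`.  When reliable peak assignments are supplied, a chain is then
#' split so that no transcriptionally internal gene carries an assigned 5'
#' peak (on the minus strand the leader is the genomically last member).
#' All maximal chains, including singletons, are returned: the TU set
#' partitions the gene set.
#'
#' @param genome an [annotated_genome()].
#' @param expression an RPKM matrix from [rpkm_matrix()].
#' @param assignments optional result of [assign_peaks()] (its `calls`
#'   table); omit (e.g. when no 5' library exists) to disable the peak rule.
#' @param max_gap largest intergenic distance that can be bridged, in bp
#'   (default 149: gaps of 150 bp or more break the TU).
#' @param min_r correlation that must be exceeded (default 0.6).
#' @param all_pairs report `min_pairwise_r` over all member pairs rather
#'   than adjacent pairs only.
#' @return object of class `tu_set`: list with `tus` (one row per TU:
#'   `tu_id`, `contig`, `strand`, `start`, `end`, `n_genes`,
#'   `min_pairwise_r`) and `members` (gene ids in transcription order).
#' @export
find_operons <- function(genome, expression, assignments = NULL,
                         max_gap = 149, min_r = 0.6, all_pairs = FALSE) {
  cds <- genome$features[genome$features$ftype == "CDS", , drop = FALSE]
  if (!nrow(cds)) stop("no CDS features")
  has_peak <- character(0)
  if (!is.null(assignments)) {
    calls <- if (is.data.frame(assignments)) assignments else assignments$calls
    has_peak <- calls$gene[calls$status %in% c("confirmed", "shifted")]
  }
  chains <- list()
  for (ctg in unique(cds$contig)) {
    for (s in c("+", "-")) {
      sub <- cds[cds$contig == ctg & cds$strand == s, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (!nrow(sub)) next
      cur <- 1L
      for (i in seq_len(nrow(sub))[-1L]) {
        gap <- sub$start[i] - sub$end[i - 1L]
        r <- suppressWarnings(cor(expression[sub$id[i - 1L], ],
                                  expression[sub$id[i], ]))
        if (is.na(r))
          message("find_operons: undefined correlation at ",
                  sub$id[i - 1L], " - ", sub$id[i], "; chain broken")
        if (gap <= max_gap && exceeds(r, min_r)) {
          cur <- c(cur, i)
        } else {
          chains[[length(chains) + 1L]] <- sub[cur, , drop = FALSE]
          cur <- i
        }
      }
      chains[[length(chains) + 1L]] <- sub[cur, , drop = FALSE]
    }
  }
  # split chains so no internal (non-leader) gene carries a reliable 5' peak
  split_chain <- function(ch) {
    n <- nrow(ch)
    if (n == 1L || !length(has_peak)) return(list(ch))
    peaked <- ch$id %in% has_peak
    cut_after <- logical(n - 1L)   # cut between genomic i and i+1
    if (ch$strand[1] == "+") {
      cut_after[which(peaked[-1L])] <- TRUE          # peaked member leads new TU
    } else {
      cut_after[which(peaked[-n])] <- TRUE           # leader is rightmost
    }
    grp <- cumsum(c(TRUE, cut_after))
    lapply(split(seq_len(n), grp), function(idx) ch[idx, , drop = FALSE])
  }
  chains <- unlist(lapply(chains, split_chain), recursive = FALSE)
  ord <- order(vapply(chains, function(ch) ch$contig[1], character(1)),
               vapply(chains, function(ch) ch$start[1], integer(1)))
  chains <- chains[ord]
  tus <- do.call(rbind, lapply(seq_along(chains), function(t) {
    ch <- chains[[t]]
    rmin <- NA_real_
    if (nrow(ch) > 1L) {
      idx <- if (all_pairs) utils::combn(nrow(ch), 2, simplify = FALSE)
             else lapply(seq_len(nrow(ch) - 1L), function(i) c(i, i + 1L))
      rmin <- min(vapply(idx, function(p)
        suppressWarnings(cor(expression[ch$id[p[1]], ],
                             expression[ch$id[p[2]], ])), numeric(1)))
    }
    data.frame(tu_id = sprintf("TU_%04d", t), contig = ch$contig[1],
               strand = ch$strand[1], start = min(ch$start),
               end = max(ch$end), n_genes = nrow(ch),
               min_pairwise_r = rmin, stringsAsFactors = FALSE)
  }))
  members <- lapply(chains, function(ch)
    if (ch$strand[1] == "+") ch$id else rev(ch$id))
  names(members) <- tus$tu_id
  structure(list(tus = tus, members = members), class = "tu_set")
}

#' @export
print.tu_set <- function(x, ...) {
  multi <- x$tus$n_genes > 1
  cat("Transcriptional units:", nrow(x$tus), "total;", sum(multi),
      "with >= 2 genes spanning", sum(x$tus$n_genes[multi]), "CDSs\n")
  invisible(x)
}

#' Compare two feature sets by sequence overlap
#'
#' Two features match when they are on the same strand and their overlap is
#' at least `min_overlap` of the shorter feature's length.  When member
#' lists are supplied (TU comparison), matched pairs additionally split into
#' exact-membership agreement vs a difference of at least one gene.
#'
#' @param ours,theirs feature tables with `id`, `contig`, `start`, `end`,
#'   `strand`.
#' @param min_overlap required fraction of the shorter feature (default 0.40).
#' @param ours_members,theirs_members optional named lists of member gene
#'   ids, keyed by feature id.
#' @return list with `matches` (ours_id, theirs_id, overlap, frac,
#'   same_members) and `counts` (`agree`, `differ`, `ours_only`,
#'   `theirs_only`).
#' @export
compare_feature_sets <- function(ours, theirs, min_overlap = 0.40,
                                 ours_members = NULL, theirs_members = NULL) {
  ours <- as.data.frame(ours); theirs <- as.data.frame(theirs)
  rows <- list()
  for (i in seq_len(nrow(ours))) {
    o <- ours[i, ]
    cand <- theirs[theirs$contig == o$contig & theirs$strand == o$strand, ,
                   drop = FALSE]
    if (!nrow(cand)) next
    ovl <- pmin(cand$end, o$end) - pmax(cand$start, o$start)
    shorter <- pmin(cand$end - cand$start, o$end - o$start)
    hit <- ovl >= min_overlap * shorter - .thr_eps
    for (j in which(hit)) {
      same <- NA
      if (!is.null(ours_members) && !is.null(theirs_members))
        same <- setequal(ours_members[[o$id]], theirs_members[[cand$id[j]]])
      rows[[length(rows) + 1L]] <-
        data.frame(ours_id = o$id, theirs_id = cand$id[j], overlap = ovl[j],
                   frac = ovl[j] / shorter[j], same_members = same,
                   stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ours_id = character(0), theirs_id = character(0),
               overlap = integer(0), frac = numeric(0), same_members = logical(0))
  matched_ours <- unique(matches$ours_id)
  have_members <- !is.null(ours_members) && !is.null(theirs_members)
  agree <- if (have_members)
    sum(vapply(matched_ours, function(id)
      any(matches$same_members[matches$ours_id == id]), logical(1)))
  else length(matched_ours)
  counts <- c(agree = agree,
              differ = length(matched_ours) - agree,
              ours_only = nrow(ours) - length(matched_ours),
              theirs_only = nrow(theirs) - length(unique(matches$theirs_id)))
  list(matches = matches, counts = counts)
}
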