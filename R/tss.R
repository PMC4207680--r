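#' Passing-Bablok robust regression
#'
#' Nonparametric line fit by the shifted median of all pairwise slopes
#' `(y_j - y_i) / (x_j - x_i)` (i < j, `x_i != x_j`): with `K` the number of
#' pairwise slopes below -1, the slope estimate is the `(N + 1)/2 + K`-th
#' ordered slope for odd `N` and the mean of the `N/2 + K`-th and
#' `N/2 + 1 + K`-th for even `N`; the intercept is `median(y - slope * x)`.
#' Robust to outliers in both variables and (approximately) equivariant
#' under exchanging x and y.
#'
#' @param x,y numeric vectors, length >= 3, x not all equal.
#' @return list with `slope`, `intercept`, `n` and `n_slopes`.
#' @export
passing_bablok <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("passing_bablok needs at least 3 finite points")
  if (length(unique(x)) < 2L) stop("passing_bablok: all x values identical")
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  use <- upper.tri(dx) & dx != 0
  s <- sort(dy[use] / dx[use])
  N <- length(s)
  K <- sum(s < -1)
  slope <- if (N %% 2L == 1L) s[(N + 1L) %/% 2L + K]
           else mean(s[N %/% 2L + K + c(0L, 1L)])
  list(slope = slope, intercept = median(y - slope * x), n = n, n_slopes = N)
}

#' Collapse a raw 5' track into called peaks
#'
#' A position is a peak when its support is >= `min_support` and is a local
#' maximum among same-strand positions within +/- `window` bp (ties keep the
#' leftmost position).
#'
#' @param track a [fiveprime_track()].
#' @param min_support minimum read support (default 5).
#' @param window local-maximum window in bp.
#' @return filtered [fiveprime_track()].
#' @export
call_peaks <- function(track, min_support = 5, window = 5) {
  keep <- logical(nrow(track))
  for (ctg in unique(track$contig)) {
    for (s in c("+", "-")) {
      idx <- which(track$contig == ctg & track$strand == s)
      if (!length(idx)) next
      pos <- track$pos[idx]; supp <- track$support[idx]
      ok <- vapply(seq_along(idx), function(k) {
        near <- abs(pos - pos[k]) <= window
        supp[k] >= min_support &&
          supp[k] >= max(supp[near]) &&
          !any(near & supp == supp[k] & pos < pos[k])
      }, logical(1))
      keep[idx[ok]] <- TRUE
    }
  }
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fiveprime_track", "data.frame")
  out
}

#' Genes suitable for 5'-peak calibration
#'
#' The calibration set consists of genes with a COG assignment and at least
#' `min_downstream` bp of same-strand feature-free space downstream of their
#' 3' end, so that trailing coverage from a downstream transcript cannot
#' contaminate the gene's own coverage.
#'
#' @param genome an [annotated_genome()].
#' @param min_downstream required clear space in bp (default 150).
#' @return character vector of gene ids.
#' @export
build_calibration_set <- function(genome, min_downstream = 150) {
  feats <- genome$features
  cds <- feats[feats$ftype == "CDS", , drop = FALSE]
  keep <- vapply(seq_len(nrow(cds)), function(i) {
    g <- cds[i, ]
    if (is.na(g$cog)) return(FALSE)
    same <- feats[feats$contig == g$contig & feats$strand == g$strand &
                    feats$id != g$id, , drop = FALSE]
    if (g$strand == "+") {
      lim <- g$end + min_downstream
      if (lim > genome$contigs[[g$contig]]) return(FALSE)
      !any(same$start < lim & same$end > g$end)
    } else {
      lim <- g$start - min_downstream
      if (lim < 0) return(FALSE)
      !any(same$end > lim & same$start < g$start)
    }
  }, logical(1))
  ids <- cds$id[keep]
  if (!length(ids)) warning("empty calibration set; calibration skipped")
  ids
}

# Strand-aware distance from a peak to a gene start: positive when the start
# lies downstream of the peak.
peak_start_dist <- function(peak_pos, start, end, strand) {
  n <- max(length(peak_pos), length(start))
  peak_pos <- rep_len(peak_pos, n); start <- rep_len(start, n)
  end <- rep_len(end, n); strand <- rep_len(strand, n)
  s5 <- ifelse(strand == "+", start, end - 1L)
  ifelse(strand == "+", s5 - peak_pos, peak_pos - s5)
}

# mean pooled (across conditions) depth over a 0-based half-open interval
pooled_mean_depth <- function(coverage, strand, contig, from, to) {
  if (to <= from) return(NA_real_)
  tot <- 0
  for (cond in coverage$conditions)
    tot <- tot + mean(depth_vector(coverage, cond, strand, contig, from, to))
  tot / length(coverage$conditions)
}

#' Calibrate 5'-peak intensity against downstream CDS coverage
#'
#' Each calibration gene is paired with its nearest same-strand peak at most
#' `max_upstream` bp upstream of the annotated start.  With
#' `x = log(mean pooled CDS depth)` -- computed excluding the first
#' `exclude_bp` bp immediately after the peak to avoid 5' library bias --
#' and `y = log(peak support)`, a Passing-Bablok line is fitted; the fit is
#' usable when the log-scale Pearson correlation reaches `min_r` and at least
#' `min_pairs` genes could be paired.  The residual `band_quantiles` define
#' the per-peak acceptance band used by [filter_reliable_peaks()].
#'
#' @param genome an [annotated_genome()].
#' @param coverage a [coverage_set()].
#' @param track a called [fiveprime_track()].
#' @param calibration_ids genes from [build_calibration_set()].
#' @param exclude_bp 5'-bias exclusion zone after the peak (default 150).
#' @param max_upstream peak-to-start pairing window (default 200).
#' @param min_r minimum calibration correlation (default 0.6).
#' @param band_quantiles residual quantiles bounding the acceptance band.
#' @param min_pairs minimum usable calibration pairs (default 10).
#' @return object of class `calibration_fit`: `slope`, `intercept`,
#'   `calibration_r`, `n_calibration`, `band` (lower/upper residual bounds),
#'   `usable`, `status` and the per-gene `pairs` table.
#' @export
calibrate_peaks <- function(genome, coverage, track, calibration_ids,
                            exclude_bp = 150, max_upstream = 200,
                            min_r = 0.6, band_quantiles = c(0.025, 0.975),
                            min_pairs = 10) {
  feats <- genome$features
  cal <- feats[feats$id %in% calibration_ids, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cal))) {
    g <- cal[i, ]
    cand <- track[track$contig == g$contig & track$strand == g$strand, ,
                  drop = FALSE]
    if (!nrow(cand)) next
    d <- peak_start_dist(cand$pos, g$start, g$end, g$strand)
    cand <- cand[d >= 0 & d <= max_upstream, , drop = FALSE]
    d <- d[d >= 0 & d <= max_upstream]
    if (!nrow(cand)) next
    k <- which.min(d)
    peak <- cand[k, ]
    if (g$strand == "+") {
      from <- max(g$start, peak$pos + exclude_bp); to <- g$end
    } else {
      from <- g$start; to <- min(g$end, peak$pos - exclude_bp + 1L)
    }
    if (to <= from) next
    m <- pooled_mean_depth(coverage, g$strand, g$contig, from, to)
    if (!is.finite(m) || m <= 0) next
    rows[[length(rows) + 1L]] <-
      data.frame(gene = g$id, peak_pos = peak$pos, support = peak$support,
                 mean_depth = m, x = log(m), y = log(peak$support))
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), peak_pos = integer(0),
               support = integer(0), mean_depth = numeric(0),
               x = numeric(0), y = numeric(0))
  fit <- list(slope = NA_real_, intercept = NA_real_,
              calibration_r = NA_real_, n_calibration = nrow(pairs),
              band = c(NA_real_, NA_real_), usable = FALSE,
              status = "ok", pairs = pairs,
              band_quantiles = band_quantiles, min_r = min_r)
  class(fit) <- "calibration_fit"
  if (nrow(pairs) < min_pairs) {
    fit$status <- sprintf("unusable: only %d calibration pairs (< %d)",
                          nrow(pairs), min_pairs)
    return(fit)
  }
  pb <- passing_bablok(pairs$x, pairs$y)
  fit$slope <- pb$slope; fit$intercept <- pb$intercept
  fit$calibration_r <- cor(pairs$x, pairs$y)
  res <- pairs$y - (fit$intercept + fit$slope * pairs$x)
  fit$band <- unname(quantile(res, band_quantiles, type = 7))
  fit$pairs$residual <- res
  if (!at_least(fit$calibration_r, min_r)) {
    fit$status <- sprintf("unusable: calibration correlation %.3f < %.2f",
                          fit$calibration_r, min_r)
  } else {
    fit$usable <- TRUE
  }
  fit
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("5' peak calibration (Passing-Bablok, log-log):\n")
  cat(sprintf("  n = %d, slope = %.3f, intercept = %.3f, r = %.3f\n",
              x$n_calibration, x$slope, x$intercept, x$calibration_r))
  cat(sprintf("  residual band [%.3f, %.3f]; %s\n", x$band[1], x$band[2],
              if (x$usable) "usable" else x$status))
  invisible(x)
}

#' Filter 5' peaks by calibration reliability
#'
#' A peak is kept when (a) its support is at least `min_support` reads and
#' (b) its `(log downstream coverage, log support)` point lies inside the
#' calibration fit's residual acceptance band.  Downstream coverage is the
#' pooled mean depth over a `window`-bp stretch starting `exclude_bp` after
#' the peak on its own strand; peaks over unexpressed ground are dropped.
#'
#' @param track a called [fiveprime_track()].
#' @param fit a usable `calibration_fit`.
#' @param coverage a [coverage_set()].
#' @param min_support hard minimum read support (default 5).
#' @param exclude_bp,window downstream-coverage geometry in bp.
#' @return the reliable [fiveprime_track()], with a `detail` attribute giving
#'   per-peak coverage, residual and the reason for any drop.
#' @export
filter_reliable_peaks <- function(track, fit, coverage, min_support = 5,
                                  exclude_bp = 150, window = 300) {
  if (!inherits(fit, "calibration_fit") || !fit$usable)
    stop("filter_reliable_peaks requires a usable calibration fit: ",
         if (inherits(fit, "calibration_fit")) fit$status else "not a fit")
  n <- nrow(track)
  mdepth <- numeric(n); res <- rep(NA_real_, n)
  reason <- character(n)
  for (k in seq_len(n)) {
    p <- track[k, ]
    len <- coverage$contigs[[p$contig]]
    if (p$strand == "+") {
      from <- min(len, p$pos + exclude_bp); to <- min(len, from + window)
    } else {
      to <- max(0L, p$pos - exclude_bp + 1L); from <- max(0L, to - window)
    }
    m <- if (to > from) pooled_mean_depth(coverage, p$strand, p$contig,
                                          from, to) else 0
    mdepth[k] <- m
    if (p$support < min_support) { reason[k] <- "low_support"; next }
    if (!is.finite(m) || m <= 0) { reason[k] <- "no_downstream_coverage"; next }
    res[k] <- log(p$support) - (fit$intercept + fit$slope * log(m))
    reason[k] <- if (res[k] < fit$band[1] || res[k] > fit$band[2])
      "outside_band" else "kept"
  }
  keep <- reason == "kept"
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fiveprime_track", "data.frame")
  detail <- cbind(as.data.frame(track), downstream_depth = mdepth,
                  residual = res, reliable = keep, reason = reason)
  attr(out, "detail") <- detail
  out
}

#' Assign reliable 5' peaks to CDSs and call start-site status
#'
#' Each peak is assigned to the same-strand CDS whose annotated start is
#' nearest, provided the start lies within `max_dist` bp downstream of the
#' peak or the peak lies within the CDS no more than `max_dist` bp past the
#' start (ties between equidistant starts are broken to the nearest and
#' logged).  Per gene: a peak more than `confirm_tol` bp downstream of the
#' annotated start (strictly inside the CDS) yields status `shifted` with
#' the strand-aware offset; a peak at/upstream of the start (within the
#' window) yields `confirmed`; genes with no assigned peak yield `no_peak`.
#'
#' @param genome an [annotated_genome()].
#' @param track the reliable [fiveprime_track()].
#' @param max_dist assignment window in bp (default 200).
#' @param confirm_tol offsets up to this count as confirmed, absorbing
#'   mapping jitter (default 3; 0 makes any downstream peak a shift call).
#' @return list with `assignments` (one row per assigned peak) and `calls`
#'   (one [StartSiteCall][assign_peaks] row per CDS: `gene`, `status`,
#'   `peak_pos`, `offset`, `support`).
#' @export
assign_peaks <- function(genome, track, max_dist = 200, confirm_tol = 3) {
  cds <- genome$features[genome$features$ftype == "CDS", , drop = FALSE]
  n <- nrow(track)
  asg <- list()
  for (k in seq_len(n)) {
    p <- track[k, ]
    cand <- cds[cds$contig == p$contig & cds$strand == p$strand, , drop = FALSE]
    if (!nrow(cand)) next
    d <- peak_start_dist(p$pos, cand$start, cand$end, cand$strand)
    inside <- p$pos >= cand$start & p$pos < cand$end
    ok <- (d >= 0 & d <= max_dist) | (inside & d < 0 & -d <= max_dist)
    if (!any(ok)) next
    cand <- cand[ok, , drop = FALSE]; d <- d[ok]
    best <- which(abs(d) == min(abs(d)))
    if (length(best) > 1L) {
      message("assign_peaks: peak ", p$contig, ":", p$pos, p$strand,
              " equidistant to ", paste(cand$id[best], collapse = ", "),
              "; keeping first")
      best <- best[1L]
    }
    asg[[length(asg) + 1L]] <-
      data.frame(contig = p$contig, pos = p$pos, strand = p$strand,
                 support = p$support, gene = cand$id[best],
                 offset = -d[best])  # >0: peak downstream of start
  }
  assignments <- if (length(asg)) do.call(rbind, asg) else
    data.frame(contig = character(0), pos = integer(0), strand = character(0),
               support = integer(0), gene = character(0), offset = integer(0))
  calls <- data.frame(gene = cds$id, status = "no_peak",
                      peak_pos = NA_integer_, offset = NA_integer_,
                      support = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(calls))) {
    sub <- assignments[assignments$gene == calls$gene[i], , drop = FALSE]
    if (!nrow(sub)) next
    j <- which.min(abs(sub$offset))
    calls$peak_pos[i] <- sub$pos[j]
    calls$offset[i] <- sub$offset[j]
    calls$support[i] <- sub$support[j]
    calls$status[i] <- if (sub$offset[j] > confirm_tol) "shifted" else "confirmed"
  }
  list(assignments = assignments, calls = calls)
}

#' Corrected gene models after start-site calls
#'
#' Genes called `shifted` get their annotated start moved to the reliable
#' peak position; all other features are returned unchanged.
#'
#' @param genome an [annotated_genome()].
#' @param calls the `calls` table from [assign_peaks()].
#' @return an [annotated_genome()] with corrected starts.
#' @export
apply_start_corrections <- function(genome, calls) {
  feats <- genome$features
  sh <- calls[calls$status == "shifted", , drop = FALSE]
  for (i in seq_len(nrow(sh))) {
    j <- match(sh$gene[i], feats$id)
    if (feats$strand[j] == "+") feats$start[j] <- sh$peak_pos[i]
    else feats$end[j] <- sh$peak_pos[i] + 1L
  }
  annotated_genome(genome$contigs, feats)
}
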