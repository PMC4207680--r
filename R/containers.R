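#' Annotated genome container
#'
#' Bundles contig lengths with a strand-aware feature table.  All internal
#' coordinates are 0-based half-open; conversion to/from the 1-based inclusive
#' GFF3 convention happens only in [read_genome_gff3()] and
#' [write_features_gff3()].
#'
#' @param contigs named integer vector of contig lengths in bp.
#' @param features data.frame with columns `id`, `contig`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `ftype` (e.g. `"CDS"`, `"novel"`, `"antisense"`,
#'   `"TU"`) and optional `cog` and `pathway` labels (NA when absent).
#'
#' @return an object of class `annotated_genome` with elements `contigs` and
#'   `features` (sorted by contig then start).
#' @export
annotated_genome <- function(contigs, features = empty_features()) {
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("contigs must be a named vector of lengths")
  contigs <- vapply(contigs, as.integer, integer(1))
  if (any(contigs <= 0L)) stop("contig lengths must be positive")
  features <- as_feature_df(features)
  validate_features(features, contigs)
  features <- features[order(features$contig, features$start, features$id), ,
                       drop = FALSE]
  rownames(features) <- NULL
  structure(list(contigs = contigs, features = features),
            class = "annotated_genome")
}

#' Build a feature table
#'
#' @param id,contig,start,end,strand,ftype,cog,pathway feature columns;
#'   coordinates 0-based half-open.
#' @return data.frame usable as the `features` slot of [annotated_genome()].
#' @export
feature_df <- function(id, contig, start, end, strand, ftype = "CDS",
                       cog = NA_character_, pathway = NA_character_) {
  data.frame(id = as.character(id), contig = as.character(contig),
             start = as.integer(start), end = as.integer(end),
             strand = as.character(strand), ftype = as.character(ftype),
             cog = as.character(cog), pathway = as.character(pathway),
             stringsAsFactors = FALSE)
}

#' @rdname feature_df
#' @export
empty_features <- function() {
  feature_df(character(0), character(0), integer(0), integer(0),
             character(0), character(0), character(0), character(0))
}

as_feature_df <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in c("cog", "pathway"))
    if (is.null(x[[col]])) x[[col]] <- rep(NA_character_, nrow(x))
  if (is.null(x$ftype)) x$ftype <- rep("CDS", nrow(x))
  need <- c("id", "contig", "start", "end", "strand", "ftype", "cog", "pathway")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("feature table lacks columns: ",
                         paste(miss, collapse = ", "))
  x <- x[, need, drop = FALSE]
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  x
}

validate_features <- function(features, contigs) {
  if (!nrow(features)) return(invisible(TRUE))
  if (anyDuplicated(features$id))
    stop("duplicate feature ids: ",
         paste(unique(features$id[duplicated(features$id)]), collapse = ", "))
  if (!all(features$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'")
  if (any(features$start >= features$end))
    stop("features must satisfy start < end (0-based half-open)")
  unknown <- setdiff(features$contig, names(contigs))
  if (length(unknown)) stop("features reference unknown contigs: ",
                            paste(unknown, collapse = ", "))
  len <- contigs[features$contig]
  bad <- features$start < 0L | features$end > len
  if (any(bad))
    stop("feature(s) outside contig bounds: ",
         paste(features$id[bad], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("Annotated genome:", length(x$contigs), "contig(s),",
      sum(x$contigs), "bp,", nrow(x$features), "feature(s)\n")
  if (nrow(x$features))
    print(table(x$features$ftype))
  invisible(x)
}

#' Stranded per-base coverage across conditions
#'
#' @param conditions ordered character vector of condition labels.
#' @param contigs named integer vector of contig lengths.
#' @param depth nested list `depth[[condition]][[strand]][[contig]]` of
#'   per-base non-negative integer vectors, one value per bp.
#' @param total_mapped named positive numeric vector of per-condition total
#'   mapped (non-rRNA) read counts.
#'
#' @return object of class `coverage_set`.
#' @export
coverage_set <- function(conditions, contigs, depth, total_mapped) {
  conditions <- as.character(conditions)
  if (!length(conditions)) stop("at least one condition required")
  if (!setequal(names(depth), conditions))
    stop("depth must have one entry per condition")
  if (is.null(names(total_mapped)) ||
      !setequal(names(total_mapped), conditions))
    stop("total_mapped must be named by condition")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0 for every condition")
  for (cond in conditions) {
    for (s in c("+", "-")) {
      if (!s %in% names(depth[[cond]]))
        stop("coverage for condition '", cond, "' lacks strand '", s,
             "'; unstranded coverage is not supported")
      for (ctg in names(contigs)) {
        v <- depth[[cond]][[s]][[ctg]]
        if (is.null(v)) stop("missing coverage for ", cond, "/", s, "/", ctg)
        if (length(v) != contigs[[ctg]])
          stop("depth array length mismatch for ", cond, "/", s, "/", ctg)
        if (any(v < 0)) stop("negative depth in ", cond, "/", s, "/", ctg)
      }
    }
  }
  structure(list(conditions = conditions,
                 contigs = vapply(contigs, as.integer, integer(1)),
                 depth = depth,
                 total_mapped = total_mapped[conditions]),
            class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat("Coverage set:", length(x$conditions), "condition(s) x 2 strands,",
      length(x$contigs), "contig(s)\n")
  cat("Conditions:", paste(x$conditions, collapse = ", "), "\n")
  invisible(x)
}

#' Extract the depth vector over an interval
#'
#' @param coverage a [coverage_set()].
#' @param condition,strand,contig which track.
#' @param start,end 0-based half-open interval; defaults to the whole contig.
#' @return integer vector of per-base depths.
#' @export
depth_vector <- function(coverage, condition, strand, contig,
                         start = 0L, end = coverage$contigs[[contig]]) {
  v <- coverage$depth[[condition]][[strand]][[contig]]
  if (is.null(v)) stop("no coverage track for ", condition, "/", strand, "/", contig)
  v[(start + 1L):end]
}

#' Pooled 5'-enriched peak track
#'
#' @param peaks data.frame with columns `contig`, `pos` (0-based), `strand`
#'   and `support` (read count).
#' @param contigs optional named contig lengths used for bounds checking.
#' @return data.frame of class `fiveprime_track`, sorted by contig/position.
#' @export
fiveprime_track <- function(peaks, contigs = NULL) {
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "strand", "support")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("peak table lacks columns: ", paste(miss, collapse = ", "))
  peaks <- peaks[, need, drop = FALSE]
  peaks$pos <- as.integer(peaks$pos)
  peaks$support <- as.integer(round(peaks$support))
  if (any(peaks$support < 1L)) stop("peak support must be >= 1")
  if (!all(peaks$strand %in% c("+", "-"))) stop("peak strand must be '+' or '-'")
  if (!is.null(contigs)) {
    bad <- peaks$pos < 0L | peaks$pos >= contigs[peaks$contig]
    if (any(is.na(bad)) || any(bad)) stop("peak position(s) outside contig bounds")
  }
  peaks <- peaks[order(peaks$contig, peaks$pos, peaks$strand), , drop = FALSE]
  rownames(peaks) <- NULL
  class(peaks) <- c("fiveprime_track", "data.frame")
  peaks
}

# 0-based position of the first transcribed base (5' end) of a feature
pos5 <- function(start, end, strand) ifelse(strand == "+", start, end - 1L)
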