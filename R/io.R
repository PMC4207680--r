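#' Read a genome annotation from GFF3
#'
#' Contig lengths are taken from `##sequence-region` pragmas (or the
#' `contig_lengths` argument when the file has none).  GFF3 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#' `COG` and `pathway` attributes are captured when present.
#'
#' @param path GFF3 file.
#' @param contig_lengths optional named integer vector overriding/replacing
#'   the `##sequence-region` pragmas.
#' @param feature_types feature types to keep (default `CDS`, `novel`,
#'   `antisense`, `TU`); `NULL` keeps everything.
#' @return an [annotated_genome()].
#' @export
read_genome_gff3 <- function(path, contig_lengths = NULL,
                             feature_types = c("CDS", "novel", "antisense", "TU")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nf != 9L)) {
    lineno <- which(body)[which(nf != 9L)[1]]
    stop("GFF3 parse error at line ", lineno, " of ", path,
         ": expected 9 tab-separated fields, found ", nf[nf != 9L][1])
  }
  if (is.null(contig_lengths)) {
    sr <- lines[startsWith(lines, "##sequence-region")]
    if (!length(sr))
      stop("no ##sequence-region pragmas in ", path,
           "; supply contig_lengths explicitly")
    parts <- strsplit(trimws(sub("^##sequence-region", "", sr)), "[ \t]+")
    contig_lengths <- vapply(parts, function(p) as.integer(p[3]), integer(1))
    names(contig_lengths) <- vapply(parts, `[`, character(1), 1)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (!length(gr))
    return(annotated_genome(contig_lengths))
  mc <- S4Vectors::mcols(gr)
  pick <- function(nm) if (nm %in% names(mc)) as.character(mc[[nm]]) else
    rep(NA_character_, length(gr))
  id <- pick("ID")
  if (anyNA(id)) {
    alt <- pick("locus_tag"); id[is.na(id)] <- alt[is.na(id)]
  }
  if (anyNA(id)) id[is.na(id)] <- paste0("feature_", which(is.na(id)))
  feats <- feature_df(
    id = id,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based inclusive -> 0-based
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ftype = as.character(mc$type),
    cog = pick("COG"),
    pathway = pick("pathway"))
  if (!is.null(feature_types))
    feats <- feats[feats$ftype %in% feature_types, , drop = FALSE]
  if (any(!feats$strand %in% c("+", "-")))
    stop("unstranded feature(s) in ", path, ": ",
         paste(head(feats$id[!feats$strand %in% c("+", "-")]), collapse = ", "))
  annotated_genome(contig_lengths, feats)
}

#' Write features as GFF3
#'
#' Internal 0-based half-open coordinates are emitted as GFF3 1-based
#' inclusive.  Features are written in deterministic (contig, start, id)
#' order with `##sequence-region` pragmas for every contig.
#'
#' @param genome an [annotated_genome()] providing contig lengths.
#' @param features feature table (defaults to the genome's own features).
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(genome, features = genome$features, path,
                                source = "cyanotx") {
  features <- as_feature_df(features)
  validate_features(features, genome$contigs)
  features <- features[order(features$contig, features$start, features$id), ,
                       drop = FALSE]
  attr_txt <- paste0("ID=", features$id)
  has_cog <- !is.na(features$cog)
  attr_txt[has_cog] <- paste0(attr_txt[has_cog], ";COG=", features$cog[has_cog])
  has_pw <- !is.na(features$pathway)
  attr_txt[has_pw] <- paste0(attr_txt[has_pw], ";pathway=", features$pathway[has_pw])
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(genome$contigs),
                     genome$contigs))
  if (nrow(features))
    lines <- c(lines,
               sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       features$contig, source, features$ftype,
                       features$start + 1L, features$end,
                       features$strand, attr_txt))
  writeLines(lines, path)
  invisible(path)
}

#' Write features as BED6
#'
#' BED uses the same 0-based half-open convention as the internal model, so
#' coordinates are emitted unchanged; score holds the feature type's rank 0.
#'
#' @param features feature table.
#' @param path output file.
#' @param genome optional [annotated_genome()] for bounds validation.
#' @return `path`, invisibly.
#' @export
write_features_bed <- function(features, path, genome = NULL) {
  features <- as_feature_df(features)
  if (!is.null(genome)) validate_features(features, genome$contigs)
  features <- features[order(features$contig, features$start, features$id), ,
                       drop = FALSE]
  lines <- 'track name="cyanotx_features"'
  if (nrow(features))
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t0\t%s", features$contig,
                              features$start, features$end, features$id,
                              features$strand))
  writeLines(lines, path)
  invisible(path)
}

# Dense per-base fill of non-overlapping (start, end, value) intervals,
# 0-based half-open, via a difference array (duplicate-start safe).
fill_dense <- function(len, start, end, value) {
  d <- numeric(len + 1L)
  if (length(start)) {
    inc <- rowsum(c(value, -value), c(start + 1L, end + 1L))
    idx <- as.integer(rownames(inc))
    keep <- idx <= len + 1L
    d[idx[keep]] <- inc[keep]
  }
  as.integer(round(cumsum(d)[seq_len(len)]))
}

read_one_bedgraph <- function(path, contigs) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "track") & !startsWith(lines, "#") &
    nzchar(trimws(lines))
  bad <- which(keep)[which(vapply(strsplit(lines[keep], "[ \t]+"),
                                  length, integer(1)) != 4L)]
  if (length(bad))
    stop("bedGraph parse error at line ", bad[1], " of ", path,
         ": expected 4 fields")
  if (!any(keep)) {
    tab <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), value = numeric(0))
  } else {
    tab <- read.table(text = lines[keep], col.names = c("contig", "start",
                                                        "end", "value"),
                      colClasses = c("character", "integer", "integer",
                                     "numeric"))
  }
  unknown <- setdiff(tab$contig, names(contigs))
  if (length(unknown))
    stop("bedGraph ", path, " references unknown contig(s): ",
         paste(unknown, collapse = ", "))
  if (any(tab$start < 0L | tab$end > contigs[tab$contig] |
          tab$start >= tab$end))
    stop("bedGraph ", path, " has interval(s) beyond contig bounds or empty")
  if (any(tab$value < 0)) stop("bedGraph ", path, " has negative depth")
  out <- lapply(names(contigs), function(ctg) {
    sub <- tab[tab$contig == ctg, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("bedGraph ", path, " has overlapping intervals on contig ", ctg)
    fill_dense(contigs[[ctg]], sub$start, sub$end, sub$value)
  })
  names(out) <- names(contigs)
  out
}

#' Read per-condition stranded coverage from bedGraph files
#'
#' @param paths nested named list `paths[[condition]][[strand]]` of bedGraph
#'   file paths, strands `"+"` and `"-"`; positions absent from a file get
#'   depth 0.  Intervals must be non-overlapping.
#' @param total_mapped named numeric vector of per-condition total mapped
#'   read counts.
#' @param contigs named integer vector of contig lengths.
#' @return a [coverage_set()].
#' @export
read_coverage_bedgraph <- function(paths, total_mapped, contigs) {
  conditions <- names(paths)
  if (is.null(conditions)) stop("paths must be named by condition")
  depth <- lapply(paths, function(by_strand) {
    if (!all(c("+", "-") %in% names(by_strand)))
      stop("each condition needs '+' and '-' strand bedGraphs; ",
           "unstranded coverage is not supported")
    lapply(by_strand[c("+", "-")], read_one_bedgraph, contigs = contigs)
  })
  coverage_set(conditions, contigs, depth, total_mapped)
}

#' Write a coverage set as bedGraph files
#'
#' One file per condition and strand, named `<condition>_<plus|minus>.bedGraph`
#' (run-length encoded, zero-depth runs omitted), plus `totals.tsv` with the
#' per-condition total mapped reads.
#'
#' @param coverage a [coverage_set()].
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_coverage_bedgraph <- function(coverage, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sname <- c(`+` = "plus", `-` = "minus")
  paths <- list()
  for (cond in coverage$conditions) {
    paths[[cond]] <- list()
    for (s in c("+", "-")) {
      path <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", cond), "_",
                                    sname[[s]], ".bedGraph"))
      lines <- character(0)
      for (ctg in names(coverage$contigs)) {
        r <- rle(coverage$depth[[cond]][[s]][[ctg]])
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths
        keep <- r$values > 0
        if (any(keep))
          lines <- c(lines, sprintf("%s\t%d\t%d\t%d", ctg, starts[keep],
                                    ends[keep], r$values[keep]))
      }
      writeLines(lines, path)
      paths[[cond]][[s]] <- path
    }
  }
  tot <- file.path(dir, "totals.tsv")
  write.table(data.frame(condition = coverage$conditions,
                         total_mapped = unname(coverage$total_mapped)),
              tot, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(bedgraph = paths, totals = tot))
}

#' Read / write a pooled 5'-peak table
#'
#' Plain TSV with columns `contig`, `pos` (0-based), `strand`, `support`.
#'
#' @param path file path.
#' @param contigs optional named contig lengths for bounds checking.
#' @return [read_fiveprime_table()]: a [fiveprime_track()].
#' @export
read_fiveprime_table <- function(path, contigs = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "character",
                                   "integer"))
  fiveprime_track(tab, contigs)
}

#' @rdname read_fiveprime_table
#' @param track a [fiveprime_track()].
#' @export
write_fiveprime_table <- function(track, path) {
  write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
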