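Package: cyanotx
Title: Transcriptome-Driven Structural Annotation and Stress-Response
    Analysis for Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Improves the structural annotation of compact bacterial
    (cyanobacterial) genomes from stranded RNA-seq coverage and a pooled
    5'-enriched library: discovers novel intergenic and antisense
    transcripts from per-base coverage, calibrates 5' peak reliability
    with Passing-Bablok regression against downstream CDS coverage,
    corrects annotated gene start sites, infers transcriptional units
    (operons) from intergenic distance, co-expression and internal 5'
    peaks, quantifies expression (RPKM), tests differential expression
    with a fixed-dispersion exact negative-binomial test, performs COG
    gene-set enrichment, clusters stress conditions, and links
    hypothetical proteins to annotated genes by co-expression.  Includes
    a synthetic-data generator that plants operons, novel transcripts,
    antisense transcripts, start-site shifts and fold changes with full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    ape,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
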