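# cyanotx

Transcriptome-driven structural annotation and stress-response analysis for
compact bacterial genomes, built around the kind of survey done for model
cyanobacteria: one stranded RNA-seq library per condition (a reference plus
several stresses sampled at two timepoints) together with a single pooled
5'-enriched library.

From per-base stranded coverage and a table of 5' peak positions, the
package:

* discovers **novel intergenic and antisense transcripts** — maximal
  intervals outside same-strand annotation with depth ≥ 5 in ≥ 3 conditions
  over more than 200 bp;
* **calibrates 5' peak reliability**: peak height is regressed on downstream
  CDS coverage (log–log) with **Passing–Bablok regression** — the shifted
  median of all pairwise slopes `(y_j − y_i)/(x_j − x_i)` — over a set of
  COG-annotated genes with ≥ 150 bp of clear downstream space; peaks are
  kept when their residual falls inside the calibration band and they carry
  ≥ 5 reads;
* **corrects start sites**: a reliable peak strictly inside a CDS (within a
  200 bp window around the annotated start) relocates the start and reports
  the offset, e.g. a 60 bp downstream shift;
* infers **transcriptional units (operons)**: same-strand tandem CDSs chain
  when the intergenic gap is < 150 bp, the Pearson correlation of their RPKM
  condition profiles exceeds 0.6 and no internal gene carries a reliable 5'
  peak;
* quantifies expression as **RPKM** = reads / (kb × mapped reads / 10⁶),
  screens per-gene positional profiles with cross-condition Spearman
  correlation, and computes genome/coding coverage fractions;
* tests **differential expression** with a fixed-dispersion exact
  negative-binomial test (two library-scaled counts conditioned on their
  sum; calls need adjusted p < 0.01 and |log2FC| > 2), rescues uncalled
  genes sharing a pathway (same sign, |Δlog2FC| ≤ 1) or a TU with a called
  gene, runs **COG enrichment** (two-sided Fisher, Benjamini–Hochberg,
  FDR 0.05), clusters conditions (1 − Pearson, complete linkage) and links
  hypothetical proteins to annotated genes co-expressed at r > 0.9.

A first-class synthetic-data generator (`simulate_transcriptome()`) plants
operons, novel and antisense transcripts, start-site shifts and fold changes
with full ground truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(cyanotx)

sim <- simulate_transcriptome(sim_config(seed = 1))
sim
#> Synthetic transcriptome (seed 1):
#>   150 genes on 200000 bp; 20 operons; 12 novel; 10 antisense; 8 start shifts
#>   11 conditions; 145 5' peaks

run <- run_pipeline(sim$genome, sim$coverage, sim$track)
run
#> cyanotx pipeline run
#>                 statistic value
#>               total_genes   150
#>   genes_without_conflicts   143
#>  genes_with_altered_start     7
#>               novel_genes    12
#>     antisense_transcripts    10
#>                 total_tus   110
#>            multi_gene_tus    20
#>   genes_in_multi_gene_tus    60
#>          tus_with_5p_peak    92
#>       tus_without_5p_peak    18
#> DE: 182 called across 10 contrasts; 0 enriched categories; 107 links

run$calibration
#> 5' peak calibration (Passing-Bablok, log-log):
#>   n = 66, slope = 1.109, intercept = 0.273, r = 0.963
#>   residual band [-0.595, 0.391]; usable

head(run$start_sites[run$start_sites$status == "shifted", ], 3)
#>          gene  status peak_pos offset support
#> 49  gene_0049 shifted    61742     60     129
#> 55  gene_0055 shifted    68840     51      74
#> 60  gene_0060 shifted    76698     53      19
```

The summary mirrors a structural-annotation report: of 150 annotated genes,
7 had their start site relocated (e.g. `gene_0049`, whose reliable 5' peak
sits 60 bp inside the annotated CDS); all 12 planted intergenic and all 10
antisense transcripts were rediscovered; the 20 planted operons appear as
the 20 multi-gene TUs covering 60 CDSs.  The calibration line (slope ≈ 1 on
the log–log scale) reflects peak heights proportional to downstream
coverage.  `run_pipeline(..., out_dir = "results/")` writes every table
(TSV), corrected gene models (GFF3), novel/TU features (BED), and the
condition dendrogram (Newick).

Real data enter through `read_genome_gff3()`, `read_coverage_bedgraph()`
and `read_fiveprime_table()`; a thin CLI lives in `inst/scripts/cyanotx`
(`cyanotx simulate`, `cyanotx run`).

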