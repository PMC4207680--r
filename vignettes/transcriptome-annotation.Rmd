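---
title: "Transcriptome-driven structural annotation of bacterial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-driven structural annotation of bacterial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanotx)
```

cyanotx turns condition-resolved stranded RNA-seq coverage of a compact
bacterial genome, plus one pooled 5'-enriched peak track, into improved
structural annotation (novel and antisense transcripts, corrected start
sites, operons) and a stress-response expression analysis.  This vignette
is the package's account of the underlying models, the choices that were
genuinely open, and what the validation on synthetic data does and does not
demonstrate.

## Coordinate and data contract

All internal coordinates are 0-based half-open; conversion to the 1-based
inclusive GFF3 convention happens only inside `read_genome_gff3()` and
`write_features_gff3()`, so there is exactly one conversion site.  Coverage
is mandatory-stranded — unstranded input is rejected rather than split
heuristically, because every downstream rule (masking, antisense calls,
peak assignment) is strand-aware.  Per-base depth is stored densely per
contig; at the few-Mbp scale of bacterial chromosomes this costs a few MB
and makes every scan O(genome length).

Read counts are reconstructed from coverage as
`sum(depth over the gene) / read_length` (default 76 bp).  The inputs are
coverage tracks, not alignments, so this conversion constant is
configurable; it cancels in RPKM ratios, in every correlation, and in the
conditional DE test, and only sets the absolute scale of counts.

## Novel transcript discovery

Positions not covered by same-strand annotation are scanned per strand.  A
transcript is a maximal interval on which at least `min_conditions = 3`
conditions hold depth ≥ `min_depth = 5` at *every* base, with length
strictly greater than 200 bp.  "Consistently" is read strictly: a one-base
dropout ends that condition's run (an optional `smooth` parameter closes
dropouts up to a given width; default 0, because the rule's published form
is silent on gaps and the strict reading is the conservative one).  The
qualifying condition subset must persist across the whole interval, which
the scanner implements via per-condition next-failure pointers (the k-th
largest pointer bounds the maximal interval from any start); overlapping
maximal intervals supported by different condition subsets are all
reported.  Intervals overlapping an opposite-strand gene by ≥ 50% of their
own length are classed antisense — the overlap fraction is our choice, as
only the existence of antisense calls is prescribed — and transcripts under
200 bp are out of scope by design (the library preparation the pipeline
models cannot see them).

## 5' peak calibration and start-site correction

A pooled 5'-enriched library yields one peak height per position, so a
*per-peak* correlation with downstream coverage is not a well-defined
quantity.  The package therefore splits the published reliability idea into
two parts:

1. **Calibration.** Genes with a COG assignment and ≥ 150 bp of same-strand
   feature-free space downstream of their 3' end form the calibration set
   (trailing coverage of downstream transcripts cannot contaminate them).
   Each is paired with its nearest same-strand peak at most 200 bp upstream
   of the annotated start.  With x = log mean CDS depth (excluding the
   first 150 bp after the peak, where 5' library chemistry inflates
   coverage — the exclusion applies to the coverage side only) and
   y = log peak support, a Passing–Bablok line is fitted.  The fit is
   usable when the Pearson correlation of (x, y) is ≥ 0.6 and ≥ 10 pairs
   exist; which correlation the 0.6 referred to is ambiguous in the
   published description, and Pearson-on-logs is the default here.
2. **Per-peak acceptance band.** The 2.5%–97.5% quantiles of the
   calibration residuals define a band; any peak whose
   (log downstream coverage, log support) point falls inside the band — and
   which carries ≥ 5 reads, a hard floor — is reliable.  For arbitrary
   peaks the downstream coverage is measured over a 300 bp window starting
   150 bp after the peak; short transcripts (< ~450 bp) can therefore lose
   their peaks, which affects nothing downstream because only CDS start
   correction and TU breaking consume reliability.

Passing–Bablok itself is the shifted median of all pairwise slopes with
offset K = #(slopes < −1), the standard nonparametric fit that is robust to
outliers in both variables; with an even number of slopes the two middle
order statistics are averaged, which is why the x↔y slope-inversion
property holds exactly only for odd counts (and to ~1e-5 otherwise).

Peak extraction from the raw track keeps positions whose support is a local
maximum within ±5 bp and ≥ 5 reads; the ±5 bp window collapses stutter
while preserving distinct TSSs (peak extraction is not prescribed
anywhere, so this is the package's definition).

Reliable peaks are assigned to the same-strand CDS with the nearest
annotated start within a 200 bp window *on either side* of the start.  The
published rule states the window only for peaks upstream of the start; we
apply the same cap to peaks inside the CDS, because an internal peak
hundreds of bp past the start is better explained as an internal TSS or
artifact than as a misannotation of that magnitude.  A peak more than
`confirm_tol = 3` bp downstream of the start (inside the CDS) produces a
`shifted` call with the strand-aware offset; within the tolerance (which
absorbs mapping jitter; set it to 0 for strict behaviour) the gene is
`confirmed`; otherwise `no_peak`.  Equidistant assignments are broken to
the nearer start and logged.

## Transcriptional units

Same-strand tandem CDSs are chained genomically left to right: a gene joins
the chain when the intergenic gap is ≤ 149 bp and the Pearson correlation
of the two genes' RPKM condition profiles exceeds 0.6.  Correlation is
evaluated on adjacent pairs (an all-pairs mode exists via `all_pairs`);
RPKM condition profiles, not per-base profiles, carry the signal.  When
peak assignments exist, chains are split so that no transcriptionally
internal gene carries a reliable peak; on the minus strand the leader is
the genomically *last* member, so the split is mirrored.  Every CDS ends up
in exactly one TU (singletons included) — a partition, which the tests
assert.  Intergenic read-through between members is simulated and visible
in coverage but is deliberately not a TU requirement; it is diagnostic
only.

## Expression and statistics

**RPKM** follows its definition exactly; conventional units are reported
(a supplementary scale used alongside the published analysis appears
internally inconsistent, and is not reproduced).  **Profile consistency**
computes, per gene, Spearman's ρ between the per-base depth profiles of
every condition pair and reports the minimum; all-tied profiles make ρ
undefined and flag the gene for review rather than silently passing.

**Differential expression** uses an exact conditional negative-binomial
test at fixed dispersion (default 0.1).  The design has one library per
condition, so replicate-based dispersion estimation is undefined; a fixed,
configurable dispersion is the honest alternative, and the dispersion-0
limit reduces to the binomial conditional (exact Poisson) test.  Counts
are scaled to the geometric-mean library size, the test conditions on
their sum, and two-sided p-values sum all splits no more probable than the
observed one.  Fold changes use a 0.5 pseudocount per condition.  Calls
require BH-adjusted p < 0.01 and |log2FC| > 2; uncalled genes are rescued
by a called gene in the same pathway with same-sign log2FC within 1 unit
("similar" had to be quantified; sign + |Δ| ≤ 1 is the package's reading)
or in the same TU.  Rescue is a single pass from the original calls —
rescued genes do not propagate further.

**Enrichment** is a two-sided Fisher exact test per COG category and
direction (two-sided p defined as the sum of all tables with probability ≤
the observed, the convention R shares), BH-adjusted across categories at
FDR 0.05.  Whether the published analysis was one- or two-sided is
unstated; two-sided is the default.  **Condition clustering** is complete
linkage on 1 − Pearson.  **Hypothetical-protein linking** treats genes
without a COG as function-unknown and reports annotated partners with
r > 0.9 from a direct pairwise screen (a gene-level dendrogram is not
needed for this and is not built).

## Numerical conventions

Thresholds are printed constants (0.6, 0.9, 150, 200, ...), and several
acceptance checks exercise data lying exactly on them.  Correlations
computed in floating point can land at 0.6 ± 1e-16 for data whose exact
correlation is 0.6, so all "strictly greater" comparisons against
configured thresholds use a guard of 1e-9: a pair at exactly the threshold
never chains, one at 0.61 always does.  Degenerate inputs follow fixed
conventions: zero counts in both conditions give p = 1 and log2FC = 0;
constant expression columns abort clustering with the column named;
undefined correlations break TU chains and are logged.

## The synthetic-data generator

`simulate_transcriptome()` emulates the survey design the pipeline
targets: one reference plus five stresses × two timepoints (11 single-
library conditions) on a 200 kb chromosome with 150 genes, 40% of them in
2–5-gene operons, 12 intergenic and 10 antisense planted transcripts, and
8 planted start-site shifts of 30–120 bp (one is always exactly 60 bp, the
canonical worked example of a misannotated start).

The noise model reflects a single library per condition:

* each gene draws **one** negative-binomial expression level
  (mean `base_depth = 30`, dispersion 0.2) shared by all conditions —
  across-gene heterogeneity, not per-condition biological replication,
  which the design does not have;
* condition effects are planted log2 multipliers per expression profile
  (operons share one profile): per stress a profile is unchanged
  (probability 0.35), mildly modulated (|log2FC| 0.4–1.5, probability
  0.5), or strongly responsive (|log2FC| 2–4.5, probability 0.15,
  recorded as DE ground truth for both timepoints, which share the
  response — this is what makes timepoint pairs co-cluster);
* per-base counts are Poisson around the gene's level times a fixed
  per-gene positional shape (mild 5'→3' linear taper ± smooth mappability-
  like bias), so positional profiles are consistent across conditions the
  way real fragment-bias patterns are;
* a per-condition log-normal depth factor (sd 0.15) models library-size
  variation;
* every transcript 5' end emits a peak with height
  `2 × mean downstream coverage × exp(N(0, 0.3))`, plus 10% spurious
  outlier peaks with coverage-independent heights;
* planted novel/antisense transcripts are floored at depth 5 in their
  three strongest conditions, so the detection rule holds by construction
  and recovery failures can only come from the caller, not the fixture.

With these defaults the generator's own invariants hold with margin:
within-operon RPKM correlations exceed the 0.6 chaining threshold for
well over 95% of adjacent pairs, and the full fixture runs through the
pipeline in seconds.  The oracle-equivalence tests use 50 random 50 kb
genomes for the scanner, 100 random datasets (n ≤ 30) for Passing–Bablok,
every 2×2 table with total ≤ 40 for Fisher, and up to 8 conditions for the
clustering oracle — sizes chosen so the whole suite runs in about a
minute.

What the generator does **not** emulate: UTR expression bleeding past gene
boundaries, rRNA contamination, multi-mapping artifacts, real operon
length/strand autocorrelation, condition-specific positional biases, or
sequence content of any kind (it is a coverage-only world).  Passing the
recovery tests therefore shows the *callers implement their rules
correctly under the stated noise model*, not that the thresholds are
optimal for any particular organism.

## Known limitations

* Fold changes are computed after total-mapped-reads scaling.  When a
  large fraction of transcription responds asymmetrically (e.g. several
  big operons induced together), total counts shift and every fold change
  is compressed toward the response — the classic composition effect that
  robust normalizations (TMM, median-of-ratios) exist to fix.  On
  simulated fixtures with unusually heavy one-sided responses this can pull
  planted 8-fold changes under the |log2FC| > 2 calling line.
* Per-peak reliability is a ~95% residual band, so roughly 1 planted start
  shift in 20 is expected to fall outside it and be missed; recovery
  rates on small planted sets (n = 8) fluctuate accordingly.
* The exact NB test's fixed dispersion is a modelling input; at a
  dispersion below the data's true one the test is anti-conservative.
* No transcript 3'-end (terminator) calling, no promoter-motif analysis,
  and no transcripts under 200 bp, by scope.
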