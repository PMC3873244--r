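# fivec — chromosome conformation capture (5C/3C) interaction analysis

`fivec` is an R package for analysing targeted chromosome-conformation
experiments over a contiguous genomic region, of the kind used to ask which
distal enhancers physically contact a gene cluster (e.g. limb enhancers and
the 5′ genes of a *Hox* cluster). It covers the complete computational path
of both assay flavours:

* **5C-seq** — many-by-many contact profiling: in-silico EcoRI digestion,
  fragment eligibility, forward/reverse primer design under an *anchored*
  ("cluster R": reverse primers on the gene cluster, forward primers tiling
  the flanking region) or *alternating* ("FR") scheme, junction-read
  filtering, interaction-frequency (IF) matrices with normalization,
  binning, smoothing, tissue subtraction and replicate correlation, and an
  insulation-based caller for TAD/sub-TAD boundaries.
* **3C-qPCR** — pairwise quantification: nine-ratio interaction
  frequencies against an equimolar BAC control library (which cancels
  primer-pair efficiency bias), replicate averaging, and cross-library
  normalization via control-region compaction profiles.
* A **synthetic-data generator** that plants known structure — restriction
  sites, distance decay, TAD/sub-TAD blocks, tissue-specific
  enhancer–promoter contacts, contaminant reads, ChIP peaks and PCR
  biases — so every stage is testable without any external data.

## The model in brief

A sequencing run yields junction reads; a read is kept iff its mapping
quality is ≥ 30, it aligns within 2 nt of its reference start, and it
contains the EcoRI site `GAATTC`. Kept reads are tallied per
(forward, reverse) primer pair and normalized to reads per thousand:

    IF(f, r) = 1000 · count(f, r) / total filtered reads of the run

Matrices are binned to 20-kb windows (per-bin mean over fragment-midpoint
assignment), smoothed with an 8-kb two-dimensional boxcar, and subtracted
between tissues (e.g. limb − head) to expose tissue-enriched contacts.
Domain boundaries are local minima of the insulation score — the mean IF
in a `w × w` square crossing the diagonal at each bin junction — kept when
their prominence exceeds 1.5 profile standard deviations.

For 3C, each primer pair is measured in three template and three
BAC-control PCRs and

    IF = (1/9) Σᵢ Σⱼ templateᵢ / controlⱼ ,

so any per-pair efficiency bias appears in numerator and denominator and
cancels. Candidate enhancers are non-promoter loci bound by RNAP2 plus at
least one other mark (Med12/p300/H3K27Ac), or by both p300 and H3K27Ac.

## Worked example

Simulate the bundled demonstration scenario — a 1-Mb region with a 10-gene
cluster split by a TAD boundary, two upstream enhancer sub-TADs, and six
limb-specific enhancer–promoter contacts — then run the anchored 5C
analysis:

```r
library(fivec)

params <- mini_hoxa_params(n_reads = 50000, seed = 7)
region <- simulate_region(params)
params <- region$params              # coordinates snapped to fragments

anchor <- GenomicRanges::GRanges("chrS",
  IRanges::IRanges(params$anchor_start, params$anchor_end))
design <- design_primers(region$fragments, region$sequence,
                         "anchored", anchor)
design
#> FivecDesign (anchored scheme): 228 forward / 51 reverse primers
#>   region: chrS:1-1000000

exp_limb <- expected_for_design(
  expected_matrix(region$fragments, params, "limb"), design)
sim <- simulate_reads(exp_limb, design, params, n_reads = 50000, seed = 8)
mapped <- map_reads(sim$reads, junction_reference(design))
flt <- filter_reads(mapped)
flt$rejected
#>  quality   offset     site unmapped
#>      600      400      250        0

tl <- tally(flt$kept)
norm <- normalize_matrix(build_matrix(tl$records, design),
                         tl$total_used_reads)
norm
#> ContactMatrix [normalized]: 228 x 51 cells (0 missing)
#>   total run reads: 48750
max(cm_values(norm))
#> [1] 5.99
```

The rejection tally reproduces the planted contamination exactly (1.2 %
low-quality, 0.8 % offset-shifted, 0.5 % site-ablated reads of 50,000),
and the normalized matrix is on the reads-per-thousand scale: its largest
cell (5.99) is a near-diagonal contact seen in ~0.6 % of all reads. From
here, `bin_matrix()`, `smooth_matrix()`, `differential_matrix()` and
`call_boundaries(insulation_profile(...))` complete the analysis;
`run_5c()` wires the whole chain from files on disk and writes matrices,
differential maps, boundary calls and a provenance JSON. The same scenario
at 10⁶ reads per tissue places all six planted limb-specific contacts in
the top 1 % of positive limb-minus-head cells.

A thin command-line wrapper over these functions is installed at
`inst/scripts/fivec-cli.R` (subcommands `simulate`, `run-5c`, `run-3c`).

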