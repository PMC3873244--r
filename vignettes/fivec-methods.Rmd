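---
title: "Methods and design of the fivec 5C/3C analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the fivec 5C/3C analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, parameter choices and
numerical conventions behind `fivec`. It is the package's design record:
wherever a convention was genuinely open, the choice and its rationale are
stated here.

## The assays and what the package computes

Chromosome conformation capture (3C) crosslinks chromatin, digests it with
a restriction enzyme (EcoRI throughout this package), religates fragments
that were spatially close, and quantifies specific ligation junctions.
5C multiplexes this: annealed forward/reverse primer pairs spanning
junctions are ligated and sequenced, so one run measures every
(forward, reverse) pair in the design. The package implements the full
downstream computation for both assays, together with a generative model
of the data so that each stage can be validated against planted truth.

## Coordinates and the digestion convention

Intervals are held as `GRanges`, i.e. 1-based closed coordinates — the
native Bioconductor convention; BED input/output converts via
`rtracklayer`, and the matrix TSV dialect (labels
`name|genome|chrom:start-end`, 1-based inclusive) matches the internal
representation directly.

An in-silico cut must be placed somewhere within the recognition site; the
assay itself fixes only fragment identity, not a sub-site offset. `fivec`
cuts at the **first base** of each `GAATTC` occurrence (`CUT_OFFSET = 0`),
so every internal fragment begins with an intact site. The payoff is
downstream: a junction reference built as *forward core + reverse core*
then contains the intact site at the joint, which is exactly the property
the read filters test. Any other fixed offset would work; this one makes
the site-containment invariant checkable by construction. Overlapping
occurrences of a user-supplied (non-EcoRI) site are resolved left to
right, greedily.

Fragment eligibility reads the size window strictly: fragments larger than
20,000 bp or smaller than 100 bp are excluded, so fragments of exactly
100 or 20,000 bp are eligible. The boundary behaviour is unit-tested.

## Primer design

Two schemes are supported. *Anchored*: reverse primers on every eligible
fragment overlapping the anchor (gene-cluster) region, forward primers on
all other eligible fragments — the design yields a cluster-versus-region
matrix. *Alternating*: forward and reverse primers alternate along the
region, starting with forward. Primer cores are the 30 nt of a fragment
abutting a cut site (3' end for forward, 5' end for reverse). Forward
primers carry the A-key sequencing tail at their 5' end; reverse primers
carry the P1-key tail at their 3' end and are 5'-phosphorylated.

Melting-temperature optimisation and genome-wide uniqueness screening are
the business of dedicated primer-design tools and are deliberately out of
scope; `design_primers()` instead accepts an exclusion list of fragment
indices. Eligible fragments shorter than the primer length cannot host a
core and are skipped with a warning.

## Read processing

Reads are mapped by exhaustive comparison against the junction reference
set, allowing a start offset of up to `max_scan = 5` nt and up to
`max_mismatch = 2` substitutions; a read maps only if exactly one
reference matches within tolerance. This deterministic stand-in
reproduces the observable needed downstream — the alignment offset —
without an external aligner. Internally the search is a hashed exact
lookup per offset with a substitution fallback narrowed by the shared
forward-core prefix, so it is vectorized and fast at simulated-run scale;
the contract is unchanged.

Filtering keeps a read iff quality ≥ 30, |offset| ≤ 2 nt, and the read
contains `GAATTC`. Three conventions:

* **Quality** is a per-read mapping-quality score; when reads arrive as
  FASTQ, the per-read minimum base quality stands in (documented in
  `read_reads_fastq()`).
* **Offset sign** is ignored — the threshold applies to the absolute
  value, since the filter is about distance from the reference start.
* **Rejection precedence** for the tally is quality → unmapped → offset →
  site. Unmapped reads have no offset, so the unmapped class is
  interposed right after quality; precedence affects only how rejected
  reads are attributed, never the kept set.

## Contact matrices

`normalize_matrix()` divides each raw count by the total filtered reads
of the run and multiplies by 1,000; the total includes every read passing
filters in that run, control-region contacts included. Normalization
conserves mass exactly (Σ normalized × total / 1000 = Σ raw) and is
invariant under jointly scaling counts and total.

`bin_matrix()` (default 20 kb) assigns each fragment pair to exactly one
bin pair by fragment midpoints and takes the per-bin mean of non-missing
cells. Midpoint assignment was chosen over overlap-weighted spreading
because it keeps the per-bin mean exact and directly testable against a
brute-force oracle. Both axes are binned from a common origin, so the
binned matrix of an alternating-design run is square with identical axes
— the form the boundary caller needs.

`smooth_matrix()` (default 8 kb) is a uniform two-dimensional boxcar over
genomic distance: each output cell is the mean of input cells whose row
and column midpoints lie within half a window of the target's. A boxcar,
not a Gaussian, because the intent is "the mean IF per window". Whether
smoothing is applied to the fragment-level matrix or after binning is
exposed as `smooth_input` in `run_5c()` (default: fragment-level); both
orders are legitimate summaries and the package does not privilege one
beyond the default.

Missing cells (`NA`) propagate through every operation and are never
imputed as zero; a zero means "measured, no reads", `NA` means "not
measured".

`differential_matrix()` subtracts matrices cell-wise (e.g. limb − head).
Subtraction of raw counts is refused: unequal sequencing depths would
dominate the difference, so only normalized (optionally binned/smoothed)
matrices may be differenced. `replicate_agreement()` is the Pearson
correlation of log(IF + ε) over shared non-missing cells, with
ε = 1/1000 — one read at the reads-per-thousand scale.

## Boundary calling

Published sub-TAD boundaries in this assay family are typically drawn by
eye on heatmaps. `fivec` replaces that with a reproducible insulation
caller — this is package methodology, not a reimplementation of a manual
step. The insulation score at the junction of bins *b* and *b + 1* is the
mean of the `w × w` square of cells crossing the boundary
(default `window_bins = 3`, i.e. 60 kb at 20-kb bins); boundaries are
local minima of this profile.

Calls are thresholded on **prominence** — the score drop between a
minimum and the higher of its flanking ridges — measured in profile
standard deviations, which makes calls invariant under rescaling the
matrix by a positive constant. The default of 1.5 SD was calibrated on
simulated matrices with planted domains (two-fold cross-boundary
contrast, blocks of ten or more 20-kb bins, 10⁵ reads): genuine
boundaries show prominences ≥ ~2.2 SD, sampling-noise minima ≤ ~1.3 SD,
so any threshold in 1.25–2 SD separates the two populations and 1.5 sits
mid-window. At those conditions the caller's pooled precision and recall
over twenty simulations exceed 0.9 (boundaries scored within ±1 bin).
Ties along flat minima break toward the lower position.

## Enhancer candidates

`call_candidates()` implements a two-branch evidence rule over ChIP peak
sets: (A) an RNAP2 peak overlapping at least one peak of any other
supplied mark, or (B) a p300 peak overlapping an H3K27Ac peak. Choices
made where the rule is silent:

* A candidate's interval is the **union** (covering range) of seed and
  directly overlapping supporting peaks — unions preserve the evidenced
  footprint and make merging stable; intersections can vanish.
* "Promoter-proximal" is ±1,000 bp around annotated promoters — the
  conventional proximal-promoter window; configurable, and stated
  prominently because the rule itself names no distance.
* Overlap means ≥ 1 bp; peak scores are not re-thresholded (significance
  is the upstream peak caller's job).
* Overlapping candidates merge; a merged candidate reachable through
  branch A is labelled A. The rule is tissue-agnostic over whatever peak
  sets are supplied.

## 3C quantification

The interaction frequency of a primer pair is the mean of the nine
template/control ratios — a literal nine-ratio mean, not a
ratio of means. Because the BAC control library contains every possible
junction at equimolar ratio, the per-pair PCR efficiency multiplies both
numerator and denominator and cancels exactly (tested: with noiseless
simulation the corrected IF equals the planted truth to machine
precision). Zero template values give IF 0; zero controls are an error —
an equimolar control cannot be zero, so a zero control indicates a failed
reaction, not a measurement.

Replicates are averaged arithmetically with the standard error of the
mean; a single replicate reports `NA` SEM (a one-point SEM is undefined).
Cross-library factors are the mean of reference/profile ratios over
shared control-region pairs (≥ 3 required); when two control regions are
available they are pooled into a single mean, with per-region factors
available by calling `cross_library_factor()` per region.

## The generative model

`contact_model_params()` fixes the planted truth. Expected contact
probability between fragments *i*, *j* (midpoint distance *d*):

E[i,j] ∝ (d + d₀)^(−α) · β_T^(#TAD boundaries crossed) ·
β_S^(#sub-TAD boundaries crossed) · γ^(pair hits a matching
tissue-specific contact), normalized to sum to one. Reads are multinomial
draws from E — `simulate_counts()` returns the counts directly;
`simulate_reads()` materializes read sequences and plants three
contaminant classes at **exact counts** (low quality < 30; start shifted
3–5 nt; site ablated by one substitution). Exact counts rather than
per-read Bernoulli draws were chosen so filter tests assert equalities,
not statistics. PCR noise in `simulate_3c()` is log-normal (positive by
construction) with configurable CV; ChIP peaks are emitted per enhancer
with per-mark dropout plus Poisson decoys.

Restriction sites are laid down by a seeded Poisson point process and the
random background sequence is scrubbed of accidental `GAATTC`
occurrences, so `digest()` reproduces the planted map exactly. Annotations
and specific-contact intervals are snapped onto eligible fragments —
otherwise a planted contact could land on an unprobeable fragment and no
design could recover it. All generators are pure functions of
(parameters, seed).

### The demonstration scenario

`mini_hoxa_params()` emulates the qualitative architecture of a *Hox*
cluster and its upstream regulatory landscape: a 1-Mb region; a 10-gene
cluster in its last 200 kb split by a TAD boundary (3′ genes in one TAD,
5′ genes extending into the other); two enhancer sub-TADs upstream; six
enhancer–promoter contacts present in "limb" and absent in "head".
Parameter values, chosen once as field-realistic: 0.25 sites/kb (~4-kb
mean fragment, the resolution of an EcoRI 5C design); α = 1 and
d₀ = 5 kb (a decay exponent near one is typical at sub-megabase scale);
β_T = 0.3, β_S = 0.6 (TADs insulate more strongly than sub-TADs);
γ = 5 for the specific contacts (a clearly visible looping enrichment);
contamination 1.2 % / 0.8 % / 0.5 % (120/80/50 planted contaminants per
10,000 reads).

### What the generator does not emulate

No polymer physics (contacts are independent draws, not a constrained
chain); no sequence-dependent primer behaviour, mappability or GC bias;
no indels or chimeric junctions; ChIP peaks have no read-level signal,
only intervals; boundary sharpness is idealized (block-constant
multipliers). Passing tests therefore demonstrate correctness of the
computations and recoverability of planted structure under the stated
noise model — not performance on real sequencing data, where mapping
artefacts and efficiency biases are richer.

## Numerical choices and degenerate inputs

* Binning/smoothing are exact means via indicator-matrix products;
  empty neighborhoods stay `NA`.
* `digest("")`, non-ACGTN sequences, non-ACGT sites, `min_bp < 1`,
  `total_run_reads ≤ 0`, non-positive bin/window sizes, window ≥ bin
  count, axis/state mismatches in subtraction, < 3 shared cells in
  correlation, < 3 shared pairs in cross-library factors, wrong 3C arity
  and non-positive controls are all hard errors, tested.
* Matrix TSVs round-trip losslessly to at least six significant digits
  (values are written at full double precision).
* Pipeline provenance JSONs contain parameters and input MD5 checksums
  but no timestamps, so reruns are byte-identical.

## Problem sizes used by the test suite

The suite validates deterministic operations exactly (enumeration and
brute-force oracles) and statistical properties at desk scale: 10,000-read
runs for filter exactness; 10⁶ multinomial reads per tissue for the
differential ranking of the six planted contacts; twenty simulations at
10⁵ reads for boundary recovery; 20 primer pairs at CV 0.1 for 3C bias
cancellation; 20,000-read read-level runs for end-to-end byte
determinism. These sizes were chosen so the full suite demonstrates every
claim in minutes on a laptop while keeping per-cell coverage comparable
to a real targeted run.

## Known limitations

* The boundary caller is a stand-in for manual delineation; its calls are
  not expected to match any published hand-drawn coordinates.
* The mapper handles substitutions only; reads with indels are unmapped.
* Primer uniqueness/TM screening must come from an external tool via the
  exclusion-list hook.
* The enhancer rule is tissue-agnostic over the peak sets it is given; if
  marks from different stages are mixed, the rule does not discount them.
* 5C matrices are not corrected for per-primer efficiency (the BAC
  correction applies to 3C); matrix-balancing normalizations (ICE) are
  out of scope.
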