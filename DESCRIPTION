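Package: fivec
Title: Chromosome Conformation Capture (5C/3C) Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of chromosome conformation capture carbon copy (5C) and
    3C experiments targeting a contiguous genomic region: in-silico restriction
    digestion and fragment eligibility, forward/reverse 5C primer design under
    anchored and alternating schemes, junction-read filtering and tallying,
    interaction-frequency matrix normalization, binning, smoothing and
    tissue subtraction, insulation-based sub-TAD boundary calling, multi-mark
    enhancer-candidate calling from ChIP peak intervals, and BAC-normalized 3C
    quantification. Includes a synthetic-data generator that plants known
    contact structure, contaminant reads, ChIP peaks and PCR biases so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
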