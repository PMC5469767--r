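Package: apaScope
Title: Alternative Polyadenylation Analysis from 3'UTR Read Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies alternative cleavage and polyadenylation
    (APA) events from per-base RNA-Seq coverage over extended 3'UTR regions.
    Implements two-isoform breakpoint inference by change-point regression on
    coverage, the percentage of distal polyA site usage index (PDUI) and its
    between-group difference (DPDUI) with Fisher exact testing and
    Benjamini-Hochberg control, 3'UTR lengthening/shortening classification,
    decomposition of gene-level FPKM into long- and short-isoform shares,
    polyadenylation-signal and position-weight-matrix motif scanning, and a
    ground-truth coverage simulator emulating a compartment-by-condition
    replicated neuronal RNA-Seq design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation.R'
    'apa.R'
    'apaScope-package.R'
    'coverage.R'
    'motif.R'
    'pipeline.R'
    'quant.R'
    'simulate.R'
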