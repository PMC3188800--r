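Package: gcbias
Title: GC-Content Bias Profiling for Sequencing Libraries and qPCR Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies base-composition (GC) bias in high-throughput
    sequencing libraries and qPCR amplicon panels. Computes windowed
    observed/expected coverage curves normalized to a mid-GC anchor,
    under-coverage fractions, per-locus representation, quality masking and
    fold-change comparisons; implements qPCR absolute quantification against
    a log-linear standard curve with background filtering, duplicate
    averaging, anchor normalization and the plateau statistic; models
    per-cycle PCR amplification efficiency as a function of fragment GC
    content with a stochastic branching-process simulator and named protocol
    presets; and generates fully synthetic inputs (composite genomes,
    size-selected fragment pools, reads with ground-truth alignments,
    emulated qPCR runs) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicAlignments,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    graphics,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
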