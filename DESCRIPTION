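Package: scMitoHet
Title: Single-Cell Mitochondrial DNA Heteroplasmy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies mitochondrial DNA heteroplasmy in single cells from
    per-cell allele-count pileups. Provides circular-genome-aware variant
    calling via a shifted-reference merge, read- and cell-level quality
    control for two-fragment long-range-PCR DNA libraries and for scRNA-seq
    libraries, an internal mitochondrial variant-effect annotator using the
    vertebrate mitochondrial genetic code, heteroplasmy classification into
    "most variable", "most impactful" and DNA-RNA "joint" mutation lists,
    and condition and modality comparison statistics. A ground-truthed
    synthetic data generator simulates heteroplasmy segregation through a
    clonal lineage bottleneck together with DNA- and RNA-arm read counts, so
    the full pipeline is exercisable and testable without raw sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    Matrix,
    jsonlite,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
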