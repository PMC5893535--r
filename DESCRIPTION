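Package: atacdar
Title: Differential Chromatin Accessibility, Stage Modeling, and
    Transcription-Factor Footprinting for ATAC-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Downstream analysis of ATAC-Seq experiments starting from
    fragment intervals and called peaks: consensus peak construction
    (proximity merging, blacklist removal), fragment counting and
    library-size normalization of the peak-by-sample signal matrix,
    global accessibility-shift summaries and MA statistics, pairwise and
    three-group differential accessibility testing with a negative
    binomial exact test, per-peak linear modeling of signal on disease
    stage with covariate adjustment and ranked selection of
    differentially accessible regions (DARs), Tn5 insertion profiles and
    footprint occupancy scores around transcription-factor motifs with
    hypergeometric footprint enrichment, peak-to-gene annotation, and
    GWAS SNP overlap summaries. Includes a synthetic cohort generator
    with planted effects for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
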