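Package: smcalign
Title: Chromosomal Arm Alignment Analysis for Bacterial Hi-C and ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify SMC-mediated alignment of the two arms of a
    circular bacterial chromosome from Hi-C and ChIP-seq data. Covers in-silico
    restriction digestion of circular genomes, read-pair classification and
    binning into contact matrices, iterative-correction matrix balancing,
    secondary-diagonal and vertical-line interaction score profiles, alignment
    extent and rate estimation, inter-arm ridge asymmetry diagnostics,
    enrichment-ratio ChIP tracks with per-gene RNA polymerase occupancy and
    transcription orientation analysis, genome inversion coordinate remapping,
    and a generative simulator of parS-loaded SMC translocation with
    transcription barriers that supplies ground-truth synthetic data for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
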