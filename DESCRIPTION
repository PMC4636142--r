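Package: flypheno
Title: Growth, Transcriptome, Sleep and Behavior Phenotyping for Drosophila Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analyses for multi-assay phenotyping of Drosophila
    mutants that broadly shift gene expression: histone-anchored absolute
    RNA-seq quantification from exon-union nucleotide coverage, wing
    trichome morphometrics and body-weight summaries, courtship-conditioning
    learning and short-term-memory indices, and sleep-bout and circadian
    rhythmicity analysis of beam-break locomotor data (chi-square
    periodogram, FFT rhythm power, actograms). Includes simulators with
    known ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
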