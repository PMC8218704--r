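Package: ddctdna
Title: Droplet Digital PCR Quantification of Circulating Tumor DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for droplet digital PCR (ddPCR) assays of
    circulating tumor DNA in liquid biopsies (plasma, serum, cerebrospinal
    and cystic fluid). Classifies two-channel droplet amplitudes into
    mutant/wild-type/double/empty populations, converts droplet counts to
    absolute concentrations by Poisson inversion, computes variant allele
    fractions, back-calculates copies per mL of the original biofluid and
    cell-free DNA mass concentration, calls sample positivity by the
    two-mutant-droplet rule, estimates assay limits of detection from
    serial-dilution experiments, calls copy-number amplification from
    target/reference ratios, post-filters structural-variant fusion
    candidates from a capture panel, and summarizes cohorts by biofluid.
    Includes a droplet-level simulator of Poisson template partitioning
    for validation without patient material.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
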