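Package: optoxr
Title: Design and Quantification Toolkit for Chimeric Light-Activated GPCRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated design of chimeric light-activated G-protein-coupled
    receptors (optoXRs) by grafting the intracellular, G-protein-coupling
    segments of a target class-A GPCR onto a rhodopsin backbone. Implements
    the legacy (V1) and optimized (V2) cut-site rule sets over an internal
    affine-gap global protein aligner, projects transmembrane topology across
    the alignment, writes designs as FASTA plus GFF3 provenance maps, and
    back-translates to codon-optimized DNA. Also provides the quantification
    math for the accompanying photoreceptor and behavior assays: baseline
    normalization and maximum relative light units for luminescent
    G-protein-coupling reporters, four-parameter logistic dose-response and
    light-intensity fits, wavelength action spectra, BRET2 ratios, larval and
    adult behavioral indices (odor preference, learning, performance, rolling
    contingency), locomotion summaries and dF/F fluorescence traces, together
    with deterministic synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    minpack.lm,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
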