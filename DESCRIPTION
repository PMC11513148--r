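Package: qcprof
Title: Membrane Protein Quality-Control Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for profiling substrates of Golgi membrane
    protein quality control. Implements SILAC (stable-isotope labeling by
    amino acids in cell culture) differential-abundance calling with a
    background-based t-test and Benjamini-Hochberg adjustment, parsing and
    orientation of predicted transmembrane-domain (TMD) topologies with
    hydrophobic-length signature statistics, shotgun-lipidomics per-class
    normalization and acyl-chain asymmetry classification with the
    Benjamini-Krieger-Yekutieli two-stage FDR, and time-averaged bilayer
    thickness (thinning) maps from membrane trajectory frames. Seeded
    synthetic-data generators emulate each input so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
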