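Package: hcscreen
Title: Arrayed siRNA High-Content Screen Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for arrayed RNAi high-content screens read out
    by a fluorescent reporter: nuclei segmentation and per-well reporter
    quantification from two-channel images, cytotoxicity filtering on cell
    counts, robust inter-plate normalization (median/MAD on the log scale),
    per-gene z-scores pooled over siRNAs and replicates, and threshold-based
    hit calling into host-cell restriction and dependency factors. Includes a
    synthetic screen generator with planted gene effects for calibration and
    power checks, a scanner for the SUMOylation consensus motif
    (psi-K-X-D/E) in capsid protein sequences, and the scrambled-control
    fold-change normalization used in validation assays.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    EBImage,
    tiff,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
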