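Package: tcrisk
Title: Length-Stratified TCR Repertoire Classification and the Lung Cancer Risk Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for T cell receptor beta-chain (TCRbeta) repertoire analysis
    oriented toward non-invasive cancer risk scoring. Reads VDJtools-style and
    AIRR Rearrangement clonotype tables; computes repertoire diversity and
    clonality statistics (D50, Shannon, Simpson, high-expansion clone counts)
    and V/J gene-usage profiles; curates length-stratified CDR3 training pools
    by frequency filtering, shared-sequence exclusion and CD-HIT-style greedy
    clustering; trains per-length binary CDR3 scorers with a fast k-mer
    reference backend; calibrates per-length probability cutoffs by ROC and
    Youden's J; aggregates flagged clone frequencies into a per-sample Lung
    Cancer Risk Index (LCRI); and runs cohort-level and longitudinal LCRI
    analyses. A seeded synthetic-repertoire simulator with power-law clone
    sizes and planted sequence motifs makes every stage testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
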