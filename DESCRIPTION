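Package: codonscan
Title: Exome-Wide Scanning for Codon-Set Enrichment and Depletion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scans a set of coding sequences (an exome) for genes that are
    enriched or depleted in a user-specified set of codons, such as the
    wobble-inosine (ADAT-dependent) codons of eukaryotes. A per-amino-acid
    background model of target-codon usage is built from the exome itself,
    each gene's expected target-codon count is derived from its amino-acid
    composition, and observed versus expected counts are compared with a
    2x2 chi-square test, corrected across the exome by the
    Benjamini-Hochberg or Bonferroni procedure. Also provides gene-body
    (metagene) profiles of target-codon frequency, tidy result tables,
    ggplot2 helpers, and a synthetic-exome generator with known ground
    truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
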