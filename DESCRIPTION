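Package: alevar
Title: Simulation and Driver-Mutation Prioritization for Adaptive
    Laboratory Evolution of Polyploid Cyanobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing adaptive laboratory evolution (ALE)
    experiments in polyploid cyanobacteria such as Synechocystis.
    Simulates serial-transfer Wright-Fisher populations with per-cell
    chromosome-copy segregation under stepwise salt stress, emulates
    clonal-isolate resequencing into polymorphism-mode read-support
    frequency tables, and prioritizes candidate driver genes by combining
    principal-component loadings with parental-versus-evolved frequency
    enrichment and a gene-level exclusion rule. Also includes growth-rate
    estimation from OD730 time series, generation accounting for
    growth-dilution cycles, a salt-step controller, and OD-normalized
    product-titre (mannitol) reporting. Readers and writers are provided
    for a minimal genome-diff dialect, frequency TSV tables, and GFF3/BED
    gene annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
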