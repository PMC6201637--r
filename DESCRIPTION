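Package: regflux
Title: Hierarchy-Aware Ranking of Transcriptional Regulators for
    Metabolite Overproduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies transcriptional regulator (TR) overexpression and
    downregulation targets for overproducing a chosen metabolite. Combines
    constraint-based flux analysis of a genome-scale metabolic model
    (per-reaction product-flux slopes from a growth-constrained sweep over
    each reaction's feasible flux range, distributed to genes through
    gene-protein-reaction rules) with normalized regulatory strengths
    estimated from producer vs. non-producer expression data on a signed
    transcriptional regulatory network. TR effects are screened by a
    randomization filter and propagated bottom-up through the cycle-pruned
    TR hierarchy to yield global effect scores used for ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
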