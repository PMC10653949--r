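Package: magdyn
Title: Functional Dynamics of Genome-Resolved Gut Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of longitudinal genome-resolved metagenomic studies.
    Distils per-genome gene annotations into pathway-completeness functional
    traits and metabolic capacity indices; partitions community diversity
    into neutral, phylogenetic and functional Hill-number components with
    Sorensen-type turnover; quantifies functional redundancy from Rao
    quadratic entropy and the Simpson index; tests directional treatment
    effects with strata-restricted PERMANOVA and canonical analysis of
    principal coordinates; tracks community-weighted mean functional
    capacities across sequential environmental disturbances with bootstrap
    intervals; and simulates complete two-species longitudinal studies with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
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
    cluster,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
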