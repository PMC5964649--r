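Package: blastotrace
Title: Cell-Lineage Analysis of Pre-Implantation Embryos from 3D+Time Tracking
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse curated cell-lineage reconstructions of
    pre-implantation mammalian embryos imaged in toto (one row per detected
    nucleus per timestep). Implements temporal rescaling anchored on the first
    blastocoel collapse detected from convex-hull volume series, geometric
    annotation of inner versus outer cells with backward propagation along the
    lineage, classification of divisions as symmetric or asymmetric, death and
    proliferation statistics (normalized death ratio, proportion of inner
    cells, binned asymmetric-division profiles, founder-clone summaries,
    coefficient of variation across embryos), an in silico transformation of
    asymmetric divisions into symmetric divisions, and a stochastic generator
    of synthetic embryo lineages with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
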