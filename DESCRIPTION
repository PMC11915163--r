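Package: cryocomm
Title: Dynamics, Co-Occurrence Networks and Assembly of Glacier-Surface Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-styled toolkit for marker-gene surveys of
    glacier-surface (and other) microbial communities sampled over seasonal
    periods. Integrates 16S/18S relative abundances with qPCR gene-copy
    totals into absolute abundances; computes alpha/beta diversity,
    ordination, PERMANOVA, Procrustes concordance, per-phylum turnover and
    Venn partitions; infers compositionally robust correlation networks
    (SparCC with bootstrap significance) and their topology; classifies
    keystone nodes by within- and among-module connectivity, quantifies
    community cohesion and its response to random phylum removal, and
    classifies taxa by the sign of their network association with a focal
    phylum; computes phylogenetic community structure (Faith PD, PSV/PSC/
    PSR/PSE, NRI/NTI, betaNTI) under tip-shuffle null models; and derives a
    nitrogen-metabolism multifunctionality index. A synthetic-community
    generator with known ground truth supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    biomformat,
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
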