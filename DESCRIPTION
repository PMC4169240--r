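Package: mtclone
Title: Clonal Expansion and Low-Level Mutation Dynamics of Mitochondrial DNA
    in Ageing Epithelium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and quantification of mitochondrial DNA (mtDNA) point
    mutation dynamics in an ageing, crypt-structured epithelium.  Provides a
    neutral Moran-drift simulator of clonal expansion in colonic crypt stem-cell
    niches, a Random Mutation Capture (RMC) mutation-frequency estimator with
    exact Poisson confidence intervals, a plasmid-calibrated heteroplasmy filter
    cascade for Ion-Torrent-style pileup counts, germline/somatic partitioning
    of paired-tissue variant tables with synonymous/non-synonymous annotation
    under the vertebrate mitochondrial genetic code, and the cohort-level
    statistical contrasts (correlations, group tests, purifying-selection
    Fisher test) used in studies of age-related mitochondrial dysfunction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
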