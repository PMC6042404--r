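Package: canyonscape
Title: Methylation Canyon Detection and DNMT3A/TET1 Chromatin Landscape Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting whole-genome bisulfite sequencing (WGBS)
    methylomes into under-methylated regions (UMRs) and large methylation
    canyons with a two-state hidden Markov model, calling differentially
    methylated cytosines and regions with a beta-posterior credible
    difference statistic, and quantifying the complementary chromatin
    occupancy of DNA methyltransferases (DNMT3A isoforms, DNMT3B1) and the
    TET1 dioxygenase: depth/input/spike-in normalization, genomic-window
    enrichment with satellite and coverage exclusions, signed log10-P
    differential occupancy, CpG-density-stratified binding with
    crossing-point estimation, scaled meta-profiles, and k-means clustering
    of promoter occupancy and differential-expression patterns. Includes a
    seeded synthetic-data generator that plants canyons, UMRs, binding
    landscapes, knockout effects, and expression archetypes with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
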