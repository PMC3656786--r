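Package: ssrpopkit
Title: Population Genetics of Multiallelic Microsatellite Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multiallelic (microsatellite/SSR) genotype
    matrices from predominantly selfing crop collections: genotype file I/O
    (Genepop, STRUCTURE, CSV dialects), per-population diversity statistics
    with rarefied allelic richness and private alleles, molecular coancestry,
    Nei minimum-distance neighbour-joining trees with locus bootstraps,
    principal coordinate analysis, a reduced STRUCTURE-style admixture Gibbs
    sampler with Evanno delta-K model choice, Weir-Cockerham F-statistics,
    multiallelic linkage-disequilibrium r2 with Hill-Weir decay fitting, a
    four-test divergent-selection scan (Ewens-Watterson, ln RH, FDIST island
    model, hierarchical island model) with consensus outlier calls and
    candidate-window arithmetic, bottleneck heterozygosity-excess and
    mode-shift tests, and a seeded forward-in-time simulator of structured,
    selfing SSR populations for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    ape,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
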