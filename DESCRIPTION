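Package: hapmsat
Title: Microsatellite Population Genetics for Haplodiploid Insects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for microsatellite (SSR) analysis of haplodiploid
    populations such as parasitoid wasps, where males are haploid and
    females diploid. Mines perfect 2-6 bp tandem repeats from sequencing
    reads with per-motif-length repeat thresholds; reads and writes GENEPOP
    and a sex-aware tabular genotype dialect; computes sex-stratified
    per-locus statistics (observed heterozygosity, Levene/Nei unbiased gene
    diversity, Weir-Cockerham inbreeding coefficient and F_ST, private and
    null-allele diagnostics); runs exact and Guo-Thompson Markov-chain
    Hardy-Weinberg tests and permutation linkage-disequilibrium tests with
    false-discovery-rate correction; converts the multilocus inbreeding
    coefficient into a sib-mating frequency and effective foundress number
    under local mate competition; and forward-simulates patch-structured
    haplodiploid populations with a controllable sib-mating rate for
    validation by parameter recovery.
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
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
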