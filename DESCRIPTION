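Package: popne
Title: Linkage Disequilibrium Decay and Effective Population Size for
    Livestock Genotype Panels and Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing the population dynamics of managed
    (especially composite cattle) populations from SNP array genotypes and
    herd books. Reads PLINK text PED/MAP genotype panels and delimited
    pedigrees, applies marker quality control (call rate, minor allele
    frequency, exact Hardy-Weinberg test, autosome restriction), computes
    pairwise linkage disequilibrium (D, D', r-squared) within a physical
    distance window, summarises LD decay over distance bins, sizes an
    equidistant SNP panel from the useful-LD crossing distance, estimates the
    historical effective population size trajectory from distance-binned LD
    (Sved-Feldman recombination mapping, sampling-bias adjustment), and
    estimates pedigree-based effective population size from increases in
    coancestry and inbreeding. Includes Wright-Fisher forward and
    hierarchical-mating pedigree simulators so every estimator is validated
    by recovery of known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
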