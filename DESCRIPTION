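Package: paleoprs
Title: Temporal Polygenic Score Trajectories and Selection Tests on Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes clumped polygenic scores for pseudo-haploid ancient
    genomes alongside modern diploid genomes, models score trajectories
    across archaeological periods (piecewise Pearson correlations with signed
    -log10 p, LOESS trend curves, adjacent-period t-tests), and tests
    trait-associated SNP sets for selective pressure using mean Hudson F_st
    against an LD/MAF-matched permutation null with Bonferroni correction.
    Includes a synthetic-data generator for temporally stratified
    pseudo-haploid cohorts with programmable allele-frequency shifts, an
    EIGENSTRAT text reader/writer, cohort and variant QC (missingness,
    geography, allele harmonization), and robustness sweeps over clumping
    and missingness thresholds with down-sampling consistency checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
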