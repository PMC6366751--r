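Package: prefqtl
Title: QTL Mapping of Mate-Preference Proportion Phenotypes in Backcross Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome scans for quantitative trait loci (QTLs) underlying
    proportion-type behavioral phenotypes, such as the fraction of courtship
    time a hybrid male directs toward one of two female types. Provides a
    two-state hidden Markov model for backcross genotype probabilities on a
    linkage map, binomial generalized linear mixed-model (GLMM) scans with an
    individual-level random intercept, permutation-based genome-wide LOD
    thresholds, penalized-LOD multi-QTL modeling with effect sizes expressed
    as a percentage of the parental-species difference, simulation-based
    assessment of the Beavis effect, windowed f_d admixture estimation from
    four-population allele frequencies, and deterministic linkage-
    disequilibrium decay arithmetic. A synthetic-data generator emulating a
    21-chromosome backcross with binomial courtship phenotypes makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    car,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
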