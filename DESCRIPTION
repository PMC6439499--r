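Package: gsimix
Title: Genetic Stock Identification and Mixed-Stock Analysis for Two
    Reference Populations
Version: 0.1.0
Authors@R: person("Arkona", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for likelihood-based genetic stock identification of
    individuals sampled from a zone where two divergent populations mix.
    Provides Weir-Cockerham FST and genotypic LD estimation, two styles of
    SNP panel high-grading (FST-ranked with LD pruning, and genome-spread
    selection on a linkage map), Rannala-Mountain genotype-likelihood
    assignment with leave-one-out power estimation, a simulation-based test
    discriminating F1 hybridization from mechanical mixing via admixture
    coefficients with credible intervals, and Bayesian binomial models of
    haul-level mixing proportions with environmental covariates, a
    second-order random-walk longitude smoother and WAIC model comparison.
    Includes a fully parameterised synthetic-data generator, Genepop/CSV
    readers and writers, and a pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
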