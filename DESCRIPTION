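Package: ssrbank
Title: Microsatellite Fingerprinting and Diversity Analysis for Germplasm Collections
Version: 1.0.0
Authors@R:
    person("IAC Germplasm Informatics", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for characterizing clonally propagated germplasm banks
    genotyped with multi-allelic co-dominant markers (SSR/microsatellites).
    Provides per-locus diversity statistics (allele counts, heterozygosity,
    polymorphism information content, discriminating power, null-allele
    frequency by expectation-maximization), Bayesian admixture clustering by
    Gibbs sampling with Evanno delta-K model selection and CLUMPP-style run
    alignment, discriminant analysis of principal components (DAPC), Rogers'
    genetic distance with neighbor-joining dendrograms and locus-bootstrap
    supports, fingerprint-based identity resolution (duplicates, synonyms,
    misnaming against a reference profile panel), core-collection selection
    maximizing allele coverage, and a synthetic-germplasm simulator with
    ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
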