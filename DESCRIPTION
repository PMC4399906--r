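Package: gwss
Title: Generalized Weighted-Sum Association Tests for Rare and Common Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-based case-control association tests that aggregate rare
    and common variants into a single per-subject burden score using one of
    four data-driven weight schemes (inverse-variance minor-allele-frequency
    weights, log odds-ratio weights, odds-ratio direction indicators, and
    direction-times-frequency weights), summarised by a Wilcoxon-type
    rank-sum or a Welch-type t statistic, optionally maximised over a set of
    variable minor-allele-frequency thresholds, with significance assessed
    by label-permutation empirical p-values in which every data-driven
    quantity is recomputed under each permuted labelling. Includes a
    genotype simulator (uniform allele-frequency spectra, AR(1)
    latent-Gaussian linkage disequilibrium, logistic liability with additive
    and any-carrier effects) and a study harness for estimating type-I error
    and power over scenario grids, plus readers for VCF and plain
    genotype-matrix input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), vcfR, mvtnorm, jsonlite, optparse, yaml
Config/testthat/edition: 3
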