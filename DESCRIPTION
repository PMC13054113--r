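Package: staygblup
Title: Single-Step Genomic BLUP for Binary Stayability Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-step genomic prediction for binary stayability (herd
    longevity) traits in beef cattle. Provides pedigree utilities (inbreeding
    by the Meuwissen-Luo recursion, sparse A-inverse by Henderson's rules,
    tabular A22), genomic relationship matrices (VanRaden method 1, tuning and
    blending against A22, APY inverse), assembly of the single-step H-inverse,
    a preconditioned conjugate-gradient solver for the linear mixed-model
    equations, a Bayesian threshold-model Gibbs sampler with liability
    augmentation and the Geweke convergence diagnostic, liability/observed
    scale conversion of variance components (Dempster-Lerner/Robertson), the
    LR (whole versus partial data) validation method, and a synthetic-data
    generator emulating multi-generation Nellore-like pedigrees, SNP
    genotypes, contemporary groups and calving histories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
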