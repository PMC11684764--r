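Package: pccollide
Title: Collider Bias from Principal Components in Admixed-Population GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and theory toolkit for studying how adjusting for
    principal components that capture local genomic features, rather than
    genome-wide ancestry, biases marginal-regression genome-wide association
    studies in two-way admixed populations. Provides a synthetic-cohort
    generator (heterogeneous admixture proportions, ancestry-differentiated
    allele frequencies, multi-region latent features, quantitative traits,
    artificial collider covariates), PCA pre-processing (minor-allele-frequency
    filtering, high-LD region exclusion, sliding-window LD pruning) with
    loading and PC-genotype correlation diagnostics, per-variant Wald
    association testing with chromosome-level spurious-association counting
    and the genomic inflation factor, and closed-form expected effect-size
    estimates under different ancestry-adjustment models, validated by a
    Monte-Carlo oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
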