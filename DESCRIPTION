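Package: nammqtl
Title: Metabolite QTL Mapping in Nested Association Mapping Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for metabolite quantitative trait
    locus (mQTL) mapping in nested association mapping (NAM) populations of
    the HEB-25 type (25 wild-donor families backcrossed once to a shared
    elite recurrent parent, then selfed to BC1S3). Provides a seeded NAM
    population and phenotype simulator with planted QTL for method
    validation; marker quality control, quantitative identity-by-state (IBS)
    genotype coding with family-wise recoding and mean imputation;
    metabolite table filtering, minimum-value imputation and grid Box-Cox
    transformation; SNP-based heritability from additive, dominance and
    epistatic genomic variance components (AI-REML) and repeatability from
    replicated control genotypes; cross-validated stepwise forward-backward
    regression GWAS with per-SNP detection rates, prediction abilities and a
    permutation-calibrated detection-rate threshold; and mQTL region
    grouping with explained variance and family-specific cumulated allele
    effects.
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
    e1071,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
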