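Package: hbmgrs
Title: Polygenic Risk Scores and Robust Skewness Analysis for High Bone
    Mass Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying high bone mass (HBM) as an extreme phenotype
    in postmenopausal cohorts: Z-score based case ascertainment and prevalence,
    an effect-size-weighted genetic risk score with mean-score imputation,
    normalization to an effective-allele-count scale and five-bin summaries,
    medcouple-based robust skewness with bootstrap confidence intervals and a
    two-group overlap comparison, dominant-model cosegregation checks in
    nuclear pedigrees, and a qPCR delta-Ct expression screen with
    reference-gene selection by minimum coefficient of variation. A synthetic
    cohort generator (Hardy-Weinberg genotypes, additive phenotype model,
    Mendelian pedigrees, Ct panels) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
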