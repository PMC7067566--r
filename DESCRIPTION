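Package: pgsport
Title: Simulation and Evaluation of Polygenic Score Portability Within an Ancestry Group
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward genetic simulation and analysis toolkit for studying how
    polygenic score (PGS) prediction accuracy varies across strata of a single
    ancestry group and across GWAS designs. Simulates biallelic SNP panels with
    block linkage disequilibrium, parental couples with optional assortative
    mating, Mendelian transmission to unrelated and sibling-pair offspring,
    additive direct effects, indirect parental genetic effects and
    stratum-specific amplification or environmental-variance scaling. Provides
    standard covariate-adjusted GWAS, logistic GWAS and sibling-difference
    GWAS, clumping plus p-value thresholding PGS construction, incremental R2
    and incremental AUC evaluation, Haseman-Elston moment estimation of SNP
    heritability, standard-error-matched comparison of sibling-based and
    standard polygenic scores, and end-to-end stratified and sibling-comparison
    experiment runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
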