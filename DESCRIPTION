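Package: diallelGP
Title: Genomic Diallel Analysis and Prediction of Maize Hybrid Responsiveness to Azospirillum Inoculation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed-model analysis of incomplete diallel mating designs with
    genomic kernels, aimed at studies of maize hybrid responsiveness to
    plant growth-promoting bacteria under nitrogen stress. Provides a
    synthetic-study generator mirroring a 19-parent / 118-hybrid greenhouse
    diallel, marker quality control and genomic relationship kernels
    (VanRaden G-BLUP and Gaussian RKHS), general combining ability (GCA) and
    specific combining ability (SCA) variance-component estimation by EM-REML
    and by Gibbs sampling, Wald and boundary-corrected likelihood-ratio tests,
    heritability and Baker's ratio, mid-parent and high-parent heterosis with
    genomic heterozygosity analytics, and two-stage genomic prediction of
    untested hybrids under CV1/CV2 cross-validation with and without
    genotype-by-environment kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
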