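Package: wavescreen
Title: Regional Genome-Wide Association Screening with Haar Wavelets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regional association testing for genome-wide association studies
    based on a Haar wavelet decomposition of genotype dosages over megabase-
    scale windows. Genotype signals are interpolated onto a dyadic grid,
    wavelet-transformed, denoised with coefficient-dependent soft thresholds,
    quantile-normalised, and reverse-regressed on the phenotype; the resulting
    regression coefficients are modelled with a constrained two-component
    Gaussian mixture, summarised into a composite region statistic, and tested
    against a Monte-Carlo-calibrated normal null. Includes an LD-block genotype
    simulator and local-polygenic phenotype models for type-I error and power
    experiments, plus Fisher's-method meta-analysis of per-region p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
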