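Package: fishqg
Title: Quantitative Genetics for Aquaculture Breeding Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for factorial-cross aquaculture
    breeding programmes. Simulates pedigrees, SNP genotypes by gene dropping
    and correlated polygenic traits; applies SNP and sample quality control;
    builds pedigree (numerator) and genomic (VanRaden) relationship matrices;
    estimates variance components, heritabilities and genetic correlations by
    average-information REML under the animal model; performs BayesCpi
    Bayesian variable-selection genome-wide association with Bayes-factor QTL
    calling and credibility intervals; and evaluates pedigree BLUP versus
    genomic GBLUP selection accuracy and dispersion bias by Monte Carlo
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
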