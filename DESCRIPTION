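Package: multibreed
Title: Multi-Breed Genomic Prediction with Across- and Within-Breed Genomic Relationships
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how quantitative
    trait locus (QTL) properties affect the accuracy of single- and
    multi-breed genomic prediction. Simulates two diverged cattle-like
    breeds under a Balding-Nichols drift model with variant classes of
    decreasing minor allele frequency, traits controlled by QTL under a
    pseudo-infinitesimal (gamma) or equal-variance ("rare allele, large
    effect") model, genomic relationship matrices rescaled to the
    ancestral base population at breed divergence, and a two-component
    GREML model with a random across-breed and within-breed animal
    effect. Includes prediction-accuracy evaluation across reference
    population designs and marker densities, and profile likelihood-ratio
    tests for separating across- and within-breed genetic variance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
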