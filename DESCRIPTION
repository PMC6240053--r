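Package: msatabc
Title: Coalescent ABC Inference of Recent Population Bottlenecks from
    Microsatellite Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies recent population bottlenecks from diploid
    microsatellite genotype panels. Implements a single-population
    continuous-time coalescent simulator with piecewise-constant effective
    size and a generalized stepwise mutation model, approximate Bayesian
    computation (rejection, multinomial-logistic model choice and
    local-linear parameter adjustment) contrasting a recent-bottleneck with a
    non-bottleneck demography, leave-one-out cross-validation and
    goodness-of-fit diagnostics, the Cornuet-Luikart heterozygosity-excess
    test under SMM/TPM/GSM mutation models, GenePop input/output with
    Hardy-Weinberg quality control, resampling-standardised diversity
    statistics (allelic richness, gene diversity, M-ratio, allele size range,
    low-frequency-allele proportion), and a synthetic multi-species panel
    generator with known demographic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
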