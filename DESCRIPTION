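Package: fluctarget
Title: Fluctuation Assays and Mutational Target-Size Models for Phage-Resistance Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting and measuring the evolution of bacteriophage
    resistance under phage-antibiotic combination treatments. Implements
    Lea-Coulson fluctuation-assay inference with partial plating (mutant-count
    distribution, maximum-likelihood mutation rates, profile-likelihood
    confidence intervals, likelihood-ratio comparisons of rates between plating
    environments), mutational target-size models that convert gene lengths and
    antibiotic-survival fractions into predicted relative resistance rates and
    mutant-spectrum distributions, greyscale-based growth scoring and MIC
    determination from agar-lawn measurements, bootstrap and chi-square
    goodness-of-fit analysis of observed mutant spectra, and a synthetic-data
    generator that simulates single-cell-founded cultures, binomial partial
    plating, and gene-resolved colony survival under a known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
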