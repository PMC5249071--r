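Package: prsreclass
Title: Bayesian SNP Likelihood-Ratio Risk Updating and Chemoprevention
    Reclassification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Updates 5-year absolute breast-cancer risk estimates with
    genotype information from a panel of independent risk SNPs, treating the
    multilocus genotype as a Bayesian likelihood ratio. Provides per-SNP
    genotype distributions in cases and controls under Hardy-Weinberg
    equilibrium and a multiplicative per-allele model, simulation of
    genotypes and screening cohorts from a binned prior-risk distribution,
    a family-history attenuation correction, ROC AUC assessment of panel
    discrimination with a closed-form oracle, and reclassification analysis
    across a treatment threshold including tiered SNP-testing strategies and
    their yield.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
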