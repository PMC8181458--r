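Package: admixpower
Title: GWAS Power and Polygenic Score Transferability in Admixed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic forward simulation of genotypes and phenotypes in a
    two-way admixed population and its two source populations. Global ancestry
    is drawn from a moment-parameterized Beta distribution, local ancestry by
    binomial sampling, and allele frequencies under the Balding-Nichols model
    with an optional minor-allele-frequency-linked F_ST increment. Effect signs
    at causal loci are tied to ancestral allele frequencies so that traits
    correlate with ancestry; phenotypes are quantitative or liability-threshold
    dichotomous with random and ancestry-correlated environment scaled to a
    target narrow-sense heritability. Per-locus linear and logistic association
    scans (with optional global-ancestry covariate) feed experiment pipelines
    that quantify discovery power, false positive rate, cross-population
    replication asymmetry, and polygenic-score transferability. A
    Weir-Cockerham F_ST estimator is included for validating the generative
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
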