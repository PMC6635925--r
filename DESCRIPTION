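Package: qstfstkit
Title: Univariate and Multivariate Qst-Fst Comparisons for Two-Species Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether quantitative-trait divergence between two
    plant species exceeds neutral expectations, tailored to nested
    greenhouse designs (species / site / accession / selfed-offspring
    replicate) with SNP genotypes from a subset of individuals. Implements
    Weir-Cockerham and Hudson multi-locus Fst estimators with locus
    bootstrap confidence intervals, SNP ascertainment filters, nested
    method-of-moments ANOVA for trait divergence and the conservative
    Qst* statistic, standard (accession-resampling) and parametric
    (chi-square mean-square) bootstrap Qst-Fst tests, and a multivariate
    G-matrix proportionality test against the neutral expectation
    rho = m * Fst * (1 - Fst). A Balding-Nichols genotype simulator and a
    nested-design phenotype simulator provide fully synthetic datasets with
    known truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
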