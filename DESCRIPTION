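Package: snpmeta
Title: Meta-Analysis of Genetic Association Studies from Genotype Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for case-control genetic association meta-analysis starting
    from per-study genotype count tables of a biallelic polymorphism.
    Implements Hardy-Weinberg equilibrium screening and quality
    classification, the five classical genetic-model contrasts (hybrid,
    homozygous, dominant, recessive, allele), Mantel-Haenszel fixed-effect
    and DerSimonian-Laird random-effects pooling with heterogeneity-driven
    model selection, subgroup and sensitivity engines, publication-bias
    diagnostics (Begg rank correlation, Egger regression, Duval-Tweedie
    trim-and-fill), false-positive report probability and Bayesian false
    discovery probability credibility assessment, and trial sequential
    analysis with O'Brien-Fleming alpha-spending boundaries.  Ships the
    genotype tables of a published meta-analysis of eNOS polymorphisms in
    type 2 diabetes as worked datasets, and a synthetic study-collection
    generator with known truth for statistical validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite, metafor
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
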