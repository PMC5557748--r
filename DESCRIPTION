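Package: symh2
Title: Heritability of Host-Associated Symbiont Community Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates narrow-sense heritability of coral-associated
    Symbiodinium (ITS-2 amplicon) communities treated as a quantitative
    host trait. Converts OTU count tables into a similarity-sensitive
    Hill diversity phenotype (the Leinster-Cobbold qD^Z metric with a
    sequence-derived similarity matrix), builds additive relationship
    matrices from half-diallel or maternal-only pedigrees, and estimates
    heritability both by a Gibbs-sampled Bayesian animal model (with DIC
    comparison of maternal-environment models) and by midparent or
    single-parent regression. Includes variance normalization via
    median-of-ratios size factors, abundance/ubiquity classification of
    OTUs, an intragenomic-variant collapsing procedure, and a synthetic
    study generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    DESeq2
Config/testthat/edition: 3
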