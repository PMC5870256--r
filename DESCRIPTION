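Package: prsadapt
Title: Polygenic Score Tests of Local Adaptation in Structured Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test for signatures of local adaptation in the genetics
    of complex traits using clumping-and-thresholding polygenic scores built
    from external GWAS summary statistics. Polygenic scores are regressed
    against site-level environmental variables with ancestry principal
    component adjustment, validated by false discovery rate control,
    permutation nulls, matched-SNP-set enrichment nulls, and an orthogonal
    (NOIA) additive/dominance/epistasis decomposition. Includes a synthetic
    cohort generator (Balding-Nichols population structure, copula-induced
    linkage disequilibrium, planted environmental selection gradients,
    simulated GWAS summary statistics and annotations) so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
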