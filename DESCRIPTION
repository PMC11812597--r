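Package: burdengwas
Title: Why GWAS and Rare-Variant Burden Tests Prioritize Different Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic models and simulators for understanding how
    common-variant association studies (GWAS) and rare loss-of-function (LoF)
    burden tests rank genes. Provides equilibrium discrete-time Wright-Fisher
    allele-frequency distributions under heterozygote selection with recurrent
    mutation and no-fixation conditioning; closed-form quantities from the
    stabilizing-selection model of association strength (trait importance and
    specificity, unbiased squared-effect estimation, realized heritability,
    the heritability flattening curve); simulators of realized heritability
    under drift and of the apparent pleiotropy of GWAS hits across many
    traits; a locus-definition and burden-overlap comparison pipeline for
    summary statistics; quantile-binned enrichment machinery with
    inverse-variance weighting; and a fully synthetic data generator with
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
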