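Package: ssblup
Title: Single-Step Genomic Evaluation of Quantitative Traits with
    Linear-Regression Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pedigree-based and single-step genomic best linear unbiased
    prediction (PBLUP, ssGBLUP) for quantitative traits under an animal
    model. Builds the numerator relationship matrix A and its sparse
    inverse with inbreeding, the VanRaden genomic relationship matrix G
    with marker quality control, and the combined single-step matrix
    H-inverse; estimates variance components and heritability by Gibbs
    sampling; and validates predictions with the Legarra-Reverter (LR)
    method, reporting population accuracy, bias and dispersion from
    partial/whole dataset comparisons. Includes a gene-dropping
    simulator that generates pedigrees, SNP genotypes and phenotypes
    with known breeding values, so the whole evaluation pipeline can be
    exercised and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Matrix,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
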