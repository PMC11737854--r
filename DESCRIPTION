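Package: tcrhla
Title: HLA-Associated Public TCR Clonotypes and Repertoire-Based HLA Typing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers T cell receptor (TCR) clonotypes associated with HLA
    alleles in cohorts of HLA-typed donors using Fisher's exact test with
    Benjamini-Hochberg false discovery control, and predicts donors' HLA types
    from repertoire data alone with per-allele L1/L2-regularized logistic
    classifiers on presence/absence of associated clonotypes. Includes a
    fuzzy (one-mismatch) matching variant, a weight-free count classifier,
    CDR3 similarity networks and repertoire feature statistics, an iterative
    procedure that computationally types untyped cohorts under a
    donor-proportional association budget, and a synthetic-cohort simulator
    with planted TCR-HLA associations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    glmnet,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
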