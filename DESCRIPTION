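Package: genpred
Title: Genomic Prediction and Core-Set Selection for Gene-Bank Collections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genomic prediction in large gene-bank collections of
    landrace accessions: genomic relationship matrices from SNP dosages,
    single-environment GBLUP and reaction-norm genotype-by-environment mixed
    models (M1-M4) fitted by Gibbs sampling or exact mixed-model equations,
    spatial adjustment of augmented field trials with a separable AR1xAR1
    residual model, population-structure correction on leading eigenvectors
    of the relationship matrix, diversity core sets (modified Rogers distance,
    Ward clustering, D-method allocation) and prediction core sets
    (PEV/reliability optimisation in a reduced eigenspace), cross-validation
    designs (TRN20-TST80, CV1, core-as-training) with accuracy and
    percent-change summaries, and a synthetic-data generator that emulates
    structured landrace collections so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
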