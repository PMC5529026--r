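Package: podometrics
Title: Stereological and Transcriptomic Quantification of Podocyte Injury
    in Experimental Diabetic Nephropathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis pipeline for longitudinal rodent models of
    diabetic nephropathy. Implements Weibel-Gomez model-based stereology
    (podocyte number, density and glomerular volume from WT-1 stained 2D
    profiles), glomerular morphometry summaries (stain-positive area per
    tuft, quadrat-based systematic sampling, ordinal fibrosis scoring
    validation), a bulk transcriptome stage (RPKM, joint fold-change /
    expression / FDR differential-expression filtering, a podocyte-specific
    mRNA composite, PCA, longitudinal gene classification and
    over-representation tests), and longitudinal clinical-endpoint
    statistics (creatinine normalization, cohort fold changes, two-way
    ANOVA with Tukey comparison families, biomarker-fibrosis correlation).
    A synthetic-data module generates every input with known ground truth:
    sectioned 3D glomeruli, negative-binomial count matrices with programmed
    differential expression, and log-normal endpoints driven by a latent
    fibrosis process, so every estimator is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
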