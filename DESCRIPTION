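Package: mixlin
Title: Linearity Evaluation of RNA-Seq Quantification Units in Titration Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess how well RNA-seq quantification units (counts, TPM,
    FPKM, log-transformed values) satisfy the linear-mixing assumption underlying
    expression deconvolution, using titration-design experiments in which two pure
    RNA samples are mixed at known proportions. Fits the mixture regression over
    all replicate combinations and aggregates coefficient, fitted-value and
    residual summaries; provides rank-concordance analysis, ROC-like residual
    curves and rescaled-model residual analysis; reads the native output tables of
    common quantifiers (HTSeq, Kallisto, Salmon, RSEM, Cufflinks); and includes a
    synthetic titration-experiment generator with known ground truth so the whole
    pipeline can be validated hermetically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
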