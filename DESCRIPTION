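Package: oculomet
Title: Discriminant Analysis of Targeted Ocular Metabolomics with Paired Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for targeted-metabolomics concentration tables from paired
    ocular study designs (two eyes per subject, two treatment groups, two
    tissues). Provides quantitation-limit filtering, log transformation and
    column scaling; PCA with Hotelling T2 screening of atypical samples;
    OPLS-DA for independent samples with cross-validated Q2, CV-ANOVA and
    response-permutation overfitting diagnostics; multilevel (within-subject)
    PLS-DA for paired eyes validated by repeated train/test resampling with
    AUROC summaries; per-metabolite paired and two-sample t tests with
    Benjamini-Hochberg false-discovery control and Venn-style set comparisons;
    and a synthetic-data generator that emulates the paired two-eye,
    two-lighting-group design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC
Config/testthat/edition: 3
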