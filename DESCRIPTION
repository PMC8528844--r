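Package: ki67window
Title: Automated Ki67 Scoring and Paired-Response Statistics for Endocrine-Therapy Window Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing endocrine-therapy response in breast-cancer
    window trials via the Ki67 proliferation index. Implements an automated
    immunohistochemistry (IHC) scoring pipeline (sliding-window patch
    classification, nucleus probability map, Gaussian nucleus map, contour
    extraction, colour/brightness DAB positivity, region-of-interest
    proliferation index and hotspot search), method-agreement statistics
    (Spearman, intraclass correlation), window-trial paired-response
    statistics (log-ratio effect sizes, responder classification,
    nonparametric arm comparisons, estradiol-gradient association), and
    expression-based proliferation readouts (knn imputation, probe collapse,
    signature scoring, empirical-Bayes moderated paired t-test). Ships a
    synthetic-data generator (H-DAB-style slide images with ground-truth
    nuclei, trial tables, expression matrices) so the whole chain is testable
    end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    limma,
    tiff,
    withr
Config/testthat/edition: 3
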