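Package: vastrac
Title: Lung Vessel Tortuosity and 3D Fractal Dimension from Thoracic CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic morphometry of the pulmonary vascular tree from
    contrast-enhanced thoracic CT volumes. Implements an end-to-end pipeline:
    total-variation denoising, lung and airway segmentation, a multiscale
    Hessian-based vessel-enhancement filter with an offset-medialness boundary
    measure, non-maxima suppression and shortest-path centerline linking,
    per-segment tortuosity via the distance metric (path length over chord
    length), and the 3D box-counting fractal dimension of the centerline tree.
    Includes synthetic vascular phantoms with analytic ground truth for
    validation, and a cohort statistics layer (Spearman correlation, linear
    regression, summary-statistics t-tests, Kruskal-Wallis, ROC analysis)
    for relating morphometry to pulmonary hemodynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    pROC,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
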