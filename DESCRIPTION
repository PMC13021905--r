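Package: keelmetrics
Title: Radiographic Densitometry and Keel Bone Morphometry for Laying Hens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies keel bone health on latero-lateral radiographs of
    laying hens. Fits a per-image four-parameter Rodbard calibration curve
    from an aluminium step wedge and converts gray values to millimetres
    aluminium equivalent (mmAleq), measures keel morphometry (total and
    ossified length, ossification degree, lateral and deviated area, the
    proportion of deviated keel bone area, and an automatically placed
    density square), encodes three-section fracture/callus scoring with its
    binary collapse, derives egg-quality and laying-performance metrics, and
    provides the cohort statistics used for such studies: exact binomial
    prevalence intervals, time-to-complete-ossification survival with
    pairwise log-rank tests and Holm adjustment, Pearson correlations with
    Fisher confidence intervals, a duplicate-assay quality-control rule,
    follicle-status assignment and relative body weight. A synthetic
    radiograph phantom generator with fully known ground truth makes every
    stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    survival,
    jsonlite,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
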