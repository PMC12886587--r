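Package: pccnets
Title: Correlation Network Analysis for Whole-Body Dynamic PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds metabolic connectivity networks from whole-body dynamic
    PET time-activity curves and static standardised uptake values (SUV).
    Implements three complementary Pearson-correlation methodologies:
    intersubject dynamic networks built from regional time-activity curves
    (d-networks), intersubject static networks built from each subject's
    vector of regional SUVs (s-networks), and intrasubject perturbation
    networks that quantify how interregional correlations change when a
    single treated subject is appended to a reference cohort (delta-PCC
    networks), together with Monte-Carlo calibration of the delta-PCC
    significance threshold, k-nearest-neighbour edge reduction, GraphML and
    edge-list export, and a synthetic whole-body cohort generator for
    testing the pipelines without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
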