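Package: fxtrend
Title: Trend Analysis and Time-Series Clustering of Per-Fraction Dose
    Deviations in Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for monitoring interfractional dosimetric change during
    fractionated radiotherapy. Per-fraction volumetric and dosimetric values
    recalculated on daily imaging are expressed as percentage deviations from
    the planning-CT baseline and analysed two ways: (i) temporal trends via
    pooled least squares with Cook's-distance outlier screening and
    random-intercept linear mixed models, with Bonferroni-corrected
    per-fraction tests locating the earliest significant deviation; and
    (ii) patient stratification via dynamic time warping of deviation time
    series, a per-patient "distinctiveness" statistic, and k-means clustering
    of the DTW distance matrix with an elbow-plus-one cluster-count rule and
    small-cluster exclusion. A calibrated synthetic-cohort generator supplies
    reproducible test beds with planted trends, serial noise, and cluster
    structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    nlme,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
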