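Package: gliomaRT
Title: Regrowth-Time Prediction for Low-Grade Gliomas After Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical modelling of the mean radiological radius of diffuse
    low-grade gliomas before and after radiotherapy. Implements a 4-parameter
    piecewise growth/shrinkage model, bound-constrained least-squares fitting of
    sparse longitudinal follow-ups, an ensemble-derived statistical prior built
    by decorrelating fitted parameters through a covariance eigen-decomposition,
    a slope-based loose-constraint estimator backed by an empirical power law,
    and Monte-Carlo virtual-patient machinery to quantify the uncertainty of
    tumor regrowth-time predictions from very few post-radiotherapy
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
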