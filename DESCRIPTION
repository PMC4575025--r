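Package: vctgrowth
Title: Growth-Rate Error Propagation and Scan-Interval Optimization for
    Volumetric CT of Small Lung Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the reproducibility of volumetric CT
    (vCT) measurements of small pulmonary nodules and its consequences
    for exponential growth-rate estimation. Implements the proportional
    volume-measurement-error model (volume SD proportional to mean
    volume), propagation of that error into the exponential growth-rate
    constant k, analytic false-positive and true-positive rates for a
    doubling-time malignancy decision window, numerical convolution of a
    lognormal malignant growth-rate distribution with the measurement
    kernel, selection of the shortest follow-up scan interval meeting a
    target false-positive rate, pairwise empirical growth-rate analysis
    of longitudinal measurement series, and a synthetic-cohort generator
    reproducing the statistical structure of repeat clinical vCT data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
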