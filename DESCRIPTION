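Package: tumoursim
Title: Monte Carlo Simulation of Hypoxic Tumour Growth and Fractionated
    Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An individual-cell Monte Carlo model of head-and-neck tumour
    growth and fractionated radiotherapy. Tumours grow from a single stem
    cell through a stem / transit-amplifying / differentiating hierarchy,
    with per-cell oxygen tensions drawn from calibrated pO2 histograms.
    Radiation cell kill follows the linear-quadratic model scaled by a
    normalised oxygen-enhancement-ratio lethality factor and a reduced
    sensitivity for non-cycling cells. Treatment simulations include
    hypoxia-induced quiescence, binomial reoxygenation increments after
    each fraction, and accelerated repopulation via a boosted symmetrical
    stem-division probability, together with biologically-effective-dose
    post-processing of the extra dose per fraction required to offset
    accelerated repopulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
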