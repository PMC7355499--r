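Package: focalmap
Title: Uncertainty-Aware Localization of Focal Cardiac Electrical Sources
    from Multi-Electrode Activation Times
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical analysis of local activation times (LATs) recorded
    by a multi-electrode mapping catheter to locate focal electrical sources
    in cardiac chambers. Models the first/last activation order of bipolar
    electrode pairs with a multinomial distribution, computes robust
    empirical-likelihood probability bounds, estimates activation
    probabilities by constrained maximum likelihood, counts sources with a
    hypothesis test, extracts most probable wave paths, estimates conduction
    velocity from electrode pairs along a path, and localizes sources by
    robust least squares over Monte-Carlo conduction-velocity draws, using
    geodesic distances on a triangulated surface mesh or Euclidean distances
    in the catheter plane. Includes a synthetic activation-time simulator
    (focal sources firing irregularly, normally distributed conduction
    velocity, Gaussian LAT noise, earliest-arrival wave collision) and a toy
    electrogram trace generator for LAT extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
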