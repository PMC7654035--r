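Package: magnetoferm
Title: Oxystat Fermentation Simulation and Magnetosome Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital-twin simulation and analytics for oxystat batch
    fermentation of magnetotactic bacteria. Provides a PI-controller
    cascade for dissolved-oxygen regulation by stepwise agitation and
    airflow, an ODE plant model of batch growth with lactate consumption,
    nitrate respiration and kLa-limited oxygen transfer, estimators for
    growth, consumption, yield and magnetite productivity, magnetosome
    particle-size statistics with rank-based tests, and a small-angle
    X-ray scattering toolkit (sphere form factor with Gaussian
    polydispersity, Guinier analyses, membrane/core size decomposition).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
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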