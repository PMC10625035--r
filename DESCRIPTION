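Package: pedipace
Title: Economic Modelling of Permanent Pacemaker Implantation After
    Congenital Heart Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level Markov cost simulation of the first twenty years
    after permanent pacemaker (PPM) implantation for postoperative heart
    block in children, with annual cycles and discounting; a closed-form
    expected-cost oracle and attrition calibration; probabilistic
    sensitivity analysis with moment-matched beta and gamma parameter
    distributions; estimation of the model's inputs (annual event
    probabilities and frequencies, length-of-stay and cost summaries,
    charge-on-LOS regressions, an indirect-cost model) from hospital event
    histories; cumulative-cost curves for clinical courses with and without
    complication, with linear extrapolation to twenty years; surgical-volume
    trend analytics (compound annual growth rates and Poisson log-linear
    trends); and a synthetic event-history generator emulating the
    institutional data the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
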