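Package: tubepower
Title: Power Analysis and Variability Modelling for WHO Tube Synergism Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based design tools for WHO tube synergism bioassays
    (pyrethroid-only versus pyrethroid-PBO). Simulates tube-level 24-hour
    mortality counts under a hierarchical logit-normal binomial model with
    within-day (tube-to-tube) and between-day random effects, scores each
    simulated experiment with a closed-form two-arm binomial GLM
    likelihood-ratio test, and estimates Monte-Carlo power across grids of
    effect sizes, tubes per arm, testing days, and variance assumptions.
    Includes minimum-detectable-difference and minimum-sample-size searches,
    a persistent power-grid cache, estimation of the within- and between-day
    variance components from tube-level data via binomial mixed models, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
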