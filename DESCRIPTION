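Package: heatRFI
Title: Heat-Stress Resilience Phenotyping and Thermoneutral-Anchored
    Residual Feed Intake for Growing Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing growth and feed efficiency of growing pigs
    under repeated short heat-stress episodes. Implements the episodic
    thermoneutral/heat-stress experiment timeline, derivation of per-period
    phenotypes (body weight gain, feed intake, metabolic body weight, feed
    conversion efficiency), the drop in gain and intake between a
    thermoneutral period and the following heat-stress period as resilience
    phenotypes, a thermoneutral-anchored residual feed intake statistic, a
    restricted maximum likelihood engine for repeated-measures mixed models
    with structured residual covariances (AR1, heterogeneous AR1, compound
    symmetry, Toeplitz, unstructured, spatial power), covariance-structure
    selection by information criteria and likelihood ratio tests, stepwise
    interaction pruning, least-squares means, adjusted (partial)
    correlations among derived traits, and a calibrated synthetic cohort
    generator that emulates the statistical structure of the experimental
    design so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
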