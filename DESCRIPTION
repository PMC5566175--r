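Package: srbsim
Title: Microsimulation of Sex Ratio at Birth Dynamics from Son Preference,
    Technology Diffusion, and Fertility Decline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An individual-based demographic microsimulation of sex ratio at
    birth (SRB) trajectories. Women who want a son practice differential
    stopping behavior; prenatal sex-determination technology diffuses along a
    logistic adoption curve; and a fertility squeeze, the ratio of a woman's
    parity to prevailing fertility levels, governs her readiness to
    sex-selectively abort. The package provides the yearly simulation engine
    with burn-in initialization and replicate ensembles, synthetic fertility
    and mortality schedule generators so every component is testable without
    external data, RMSE-based calibration on a Latin hypercube design with a
    regression metamodel, ANOVA variance decomposition for sensitivity
    analysis, and counterfactual scenario runners.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    lhs,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
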