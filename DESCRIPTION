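Package: smokesim
Type: Package
Title: Markov Simulation of Smoking Prevalence, Tobacco Control
    Policies, and Vaping-Era Counterfactual Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discrete-time cohort simulation of cigarette smoking for a
    national population: the population evolves by single year of age and
    sex through births, deaths, and net migration, while smoking states
    (never, current, former by years quit) follow a first-order Markov
    process driven by net initiation, cessation, and relapse.  Tobacco
    control policies (taxes, smoke-free air laws, marketing restrictions,
    health warnings, media campaigns, cessation treatment, youth access,
    menthol bans) act as multiplicative effect sizes on prevalence,
    initiation, and cessation.  Status-specific death rates derived from
    relative risks yield smoking-attributable deaths.  On top of the
    engine, the package implements an indirect counterfactual method for
    inferring the impact of nicotine vaping products on smoking
    prevalence: calibrated no-vaping projections are compared with
    national survey series, the gap is annualized into per-year
    adjustments, and adjusted projections are differenced to estimate
    deaths averted.  A synthetic-country generator with known ground
    truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
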