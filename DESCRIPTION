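Package: ratiopkpd
Title: Population PK/PD Modelling of ACE Inhibition via the Angiotensin II/I Ratio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic/pharmacodynamic analysis of
    enalaprilat and the angiotensin II/angiotensin I ratio, a dimensionless
    readout of in-vivo ACE activity. Implements transit-compartment oral
    absorption into a two-compartment disposition system with a semi-analytic
    solver, an effect-compartment sigmoid Imax pharmacodynamic model, a
    hierarchical lognormal inter-individual variability layer with correlated
    random effects, interval-censored handling of below-quantification-limit
    concentrations, SAEM and quadrature-based maximum-likelihood estimation,
    stepwise covariate search, visual predictive checks, hysteresis and
    percent-change diagnostics, and seeded synthetic-study generators for a
    rich single-dose adult design and a sparse repeated-dose paediatric design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
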