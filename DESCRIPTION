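Package: ebopk
Title: Population Pharmacokinetics of Epetraborole with Transit-Compartment
    Absorption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Population pharmacokinetic analysis pipeline for epetraborole,
    an oral leucyl-tRNA synthetase inhibitor in development for
    Mycobacterium avium complex (MAC) lung disease. Implements a
    three-compartment disposition model with linear elimination, IV infusion
    input and transit-compartment oral absorption with separate fed and
    fasted absorption rates and an absolute bioavailability term, solved in
    closed form; allometric body-weight scaling of clearances and volumes;
    log-normal interindividual variability; nonlinear mixed-effects
    estimation by the Laplace approximation with empirical Bayes estimates
    and shrinkage reporting; goodness-of-fit residuals and
    prediction-corrected visual predictive checks; and a synthetic
    trial-program generator emulating a pooled Phase 1/Phase 2 design for
    end-to-end testing and clinical trial simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
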