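Package: rhonobist
Title: Bistability Analysis of the RhoA-Nitric-Oxide Mechano-Signaling Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to build and analyse ordinary-differential-equation models
    of the mutual antagonism between the RhoA/ROCK contractility pathway and
    the eNOS/NO/cGMP/PKG relaxation pathway, with an optional cytoskeletal
    tension variable that closes a mechanical positive-feedback loop. The
    package assembles typed reaction networks into evaluable rate fields,
    integrates them to steady state, detects multistability by seeded
    multistart ensembles and extreme initializations, maps bistable regimes
    by pseudo-arclength continuation and quasi-static hysteresis sweeps, and
    quantifies robustness of bistability under single-parameter percentage
    perturbations. Includes a minimal two-node mutual-antagonism model, a
    biochemical RhoA-NO network (31 reactions, 11 equations) and a
    tension-extended variant (12 equations, 36 rate parameters).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
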