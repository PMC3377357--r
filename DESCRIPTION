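Package: bcmpbpk
Title: Physiologically Based Pharmacokinetic Modelling of Bromochloromethane
    Closed-Chamber Gas Uptake in Rats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A seven-compartment flow-limited physiologically based
    pharmacokinetic (PBPK) model for bromochloromethane (BCM) vapor uptake in
    closed recirculating chambers, with two competing descriptions of hepatic
    and renal metabolism: a two-pathway model (saturable CYP2E1 oxidation plus
    first-order glutathione-S-transferase conjugation) and a single-enzyme
    two-binding-site model with atypical kinetics. Provides stiff ODE
    simulation of chamber depletion experiments, synthetic dataset generation,
    derivative-free estimation of metabolic parameters from multi-concentration
    chamber time courses on the natural-log scale, and normalized local
    sensitivity analysis with identifiability diagnostics and sensitivity
    surfaces over parameter-variability ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
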