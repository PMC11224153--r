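Package: gravicor
Title: Lumped-Parameter Cardiopulmonary Hemodynamics Across Gravitational
    Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A closed-loop, 21-compartment lumped-parameter (0D) model of
    the human cardiopulmonary system with time-varying elastance heart
    chambers, ideal diode valves, hydrostatic gravity terms, lymphatic
    return and a set-point baroreflex controller.  Simulates posture and
    gravity protocols such as the standing-1G to microgravity transition,
    parameterizes heart failure with reduced (HFrEF) and preserved (HFpEF)
    ejection fraction, applies a diuretic volume-reduction countermeasure,
    and reduces simulated time series to beat-averaged hemodynamic
    summaries, pressure-volume loops, ventriculo-arterial coupling and
    transition reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
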