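Package: methanobatch
Title: Coupled Microbial Methanation and Gas-Liquid Mass Transfer in
    Pressurized Batch Reactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and calibrates the growth of hydrogenotrophic
    methanogens in sealed pressurized batch reactors. The model couples
    double-Monod dual-substrate growth kinetics (hydrogen and carbon
    dioxide) with two-film gas-liquid mass transfer under Henry's law,
    tracking component moles in both phases and closing the gas phase
    with the ideal gas law so that the recorded pressure decline can be
    matched. Includes a calibration workflow that recovers the maximum
    growth rate, yield coefficient, mass-transfer coefficient and lag
    times from pressure traces and sparse cell counts, refill-cycle
    experiments, a synthetic-observation generator for
    simulate-then-recover validation, and a specific-contact-area
    upscaling of the mass-transfer coefficient to water-wet porous media
    relevant to underground hydrogen storage screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
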