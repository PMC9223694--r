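Package: hsrdyn
Title: Single-Cell Heat Shock Response Kinetics and Chaperone Expression Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic modeling and statistical analysis of the HSF1-mediated
    heat shock response at single-cell resolution. Implements a
    temperature-driven ODE model of the HSF1/HSP70 titration network with a
    nuclear-stress-body foci-fraction readout, a synthetic single-cell
    trajectory generator with log-normal expression heterogeneity,
    population-level response statistics (responder fractions, amplitude
    distributions, relaxation indices, ratio-binned activation functions),
    and a model-based inference that reconstructs the population
    distribution of initial chaperone concentration from per-cell foci
    dynamics and total HSF1 fluorescence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
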