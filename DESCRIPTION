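Package: srngrowth
Title: Scalable Reaction Networks and Long-Term Exponential Growth
Version: 0.1.0
Authors@R:
    person("SRN", "Maintainers", email = "srngrowth@example.org", role = c("aut", "cre"))
Description: Build nonlinear reaction networks whose flux functions are scalable
    (positive and smooth on the positive quadrant, upstream-limited, and degree-1
    homogeneous), integrate their biomass dynamics and the rescaled dynamics of the
    composition vector on the unit simplex, and compute long-term exponential growth
    rates as Birkhoff time averages or as space averages over ergodic occupation
    measures. Includes attractor classification (fixed point, limit cycle,
    quasiperiodic, chaotic, heteroclinic), largest-Lyapunov-exponent estimation,
    stochastic simplex dynamics, detection of autocatalytic circuits from reaction
    maintenance sets, a model zoo (repressilator growth circuits, cross-feeding
    Lotka-Volterra communities, chemostats, a biosynthesis toy model), and seeded
    random-network generators for large-scale screening.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
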