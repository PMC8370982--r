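Package: dynregime
Title: Detecting Alternative Dynamical Attractors in Ecological Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A formal statistical test for whether two segments of an ecological
    time series are governed by qualitatively different dynamical attractors.
    Attractors are reconstructed from each regime by Takens delay embedding;
    simplex projection (univariate) or cross-mapping (multivariate) forecasts of
    one regime are made from its own library and from the contrasting regime's
    library, and the difference in mean absolute prediction error is assessed
    with a one-sided permutation test. Includes the two simulation models used
    to characterise the test: a tri-trophic food-chain ODE whose resource
    carrying capacity switches the attractor between equilibrium, limit cycles
    and chaos, and a one-dimensional stochastic harvesting model with
    alternative stable states, together with replicated detection-probability
    landscape experiments over series length, observation noise and harvest
    rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
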