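Package: pirodyn
Title: Nonlinear Dynamics of Repeated Motor Tasks: Attractor
    Reconstruction and Recurrence Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for nonlinear time-series analysis of short, repeated
    motor tasks such as dance pirouettes. Builds long group-level composite
    series from many short per-subject kinematic trials (resampling,
    normalization, seeded shuffling, alternate time-reversal,
    quantile-based peak reduction), characterizes the result (rescaled-range
    Hurst exponent, windowed-drift stationarity check, IAAFT surrogate
    nonlinearity test, Rosenstein largest Lyapunov exponent), reconstructs
    attractors by Takens delay embedding with average-mutual-information
    delay and false-nearest-neighbor dimension selection (global and
    directional settings), compares attractor geometry via convex-hull
    volumes, and performs recurrence quantification analysis (recurrence
    rate, determinism, longest diagonal line, diagonal-line entropy,
    laminarity, trapping time). A synthetic pirouette-cohort generator and
    reference-signal generators (fractional Gaussian noise, Lorenz system,
    logistic map) support testing every stage without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
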