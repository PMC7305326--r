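Package: sanhrv
Title: Separating Sinoatrial and Autonomic Signatures in Beat-Interval Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for heart rate variability (HRV) analysis aimed at separating
    the sinoatrial-node (SAN) and autonomic-nervous-system (ANS) contributions to
    beat (RR) interval time series. Provides seeded synthetic-data generators
    (ideal white/pink/Brownian interval noise, basal-like and blockade-like
    surrogates, ectopic-beat injection), RR-interval construction and ectopic
    filtering (range, moving-average and quotient filters, transient removal,
    windowing and window quality control), a full HRV metric battery
    (time-domain, autoregressive and Welch spectra with band decomposition,
    sample entropy and multiscale entropy, detrended fluctuation analysis with
    two-range slopes and base level, spectral fractal exponent), a generative
    model of the ANS contribution (two sinusoids embedded in white noise), an
    exponentially decaying filter that attenuates the ANS contribution, and a
    coupled-oscillator model of the sinoatrial pacemaker's calcium and membrane
    clocks with simulation, transfer-function evaluation, parameter estimation
    and coupling-coefficient scans.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
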