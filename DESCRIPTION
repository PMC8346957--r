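Package: fracdrude
Title: Fractional-Derivative Drude Dielectric Model with FDTD Simulation
    and Tissue Spectrum Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-parameter fractional-derivative generalisation of
    the Drude dielectric model. Provides truncated Grunwald-Letnikov weight
    tables and discrete fractional derivatives of sampled signals, closed-form
    susceptibility, permittivity, wave-vector and conductivity spectra
    (with Debye, Cole-Cole and Havriliak-Negami reference models), a 1-D
    Yee-grid FDTD simulator in which the fractional medium is advanced by an
    auxiliary differential equation with N-term polarization memory, a
    validation harness that measures the numerical susceptibility against the
    analytic formula (accuracy tables, stability scans, memory-depth sweeps,
    power-law absorption slopes), and a multi-start nonlinear least-squares
    fitter for broadband tissue permittivity spectra, including a synthetic
    two-term Cole-Cole spectrum generator for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    lhs,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
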