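Package: cordicpc
Title: Bit-Accurate CORDIC Fixed-Point Emulation of a Cerebellar Purkinje
    Cell Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Software emulator and validation suite for a multiplier-less,
    fixed-point implementation of the five-channel (Kramer-type) cerebellar
    Purkinje cell model. Provides a double-precision reference integrator,
    a hardware-faithful arithmetic backend in which every exponential,
    division and multiplication is computed with CORDIC hyperbolic/linear
    rotations, canonical-signed-digit shift-add constant multipliers and
    functional shift multipliers over Q-format fixed-point numbers, spike
    train comparison metrics (maximum absolute error, RMSE, spike-timing
    error, Pearson correlation, spiking-mode classification), fast-slow
    bifurcation analysis of the bursting mechanism, and a two-cell coupled
    network.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
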