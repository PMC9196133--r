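Package: mfnet
Title: Mean-Field Analysis of Neuronal Network Models
Version: 0.1.0
Authors@R:
    person("mfnet", "developers", email = "mfnet@example.org", role = c("aut", "cre"))
Description: Analytical mean-field methods for networks of leaky
    integrate-and-fire (LIF) and binary neurons: stationary self-consistent
    firing rates via the Siegert first-passage formula (white and
    fast colored noise), linear-response transfer functions based on
    parabolic cylinder functions, population-rate power spectra from the
    effective connectivity matrix, an eigenvalue sensitivity measure
    relating connectivity to spectral peaks, a mapping from spiking to
    low-pass rate models, and linear stability analysis of delayed,
    spatially structured rate networks via the multi-branch Lambert W
    function. Includes a yaml parameter-file reader with unit handling,
    a result cache with HDF5 export, deterministic fixture generators,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    jsonlite,
    rhdf5,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
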