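Package: kvcert
Title: Kilovoltage Contrast-Enhanced Radiotherapy Dose Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates contrast-enhanced radiotherapy delivered with a
    kilovoltage CT scanner beam. Provides bundled photon interaction data
    with material mixing and half-value-layer / effective-energy analysis,
    a calibrated 120 kVp tube spectrum with bowtie filter geometry, a
    synthetic abdominal voxel phantom with an iodinated (Lipiodol-like)
    tumour insert, a voxel Monte Carlo photon transport engine with
    Woodcock delta tracking and local electron energy deposition, arc
    delivery planning normalised to a dose-volume prescription, and
    dose-volume histogram metrics with constraint checking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
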