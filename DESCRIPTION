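Package: saxshell
Title: Unified-Model Fitting and Invariant Composition Analysis for
    Small-Angle X-ray Scattering from Porous Shells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the nanoscale structure of porous
    biopolymer shells (such as the regenerated-cellulose hydrogel coating
    of oil-in-water emulsion droplets) from one-dimensional
    absolute-calibrated small-angle X-ray scattering curves. Implements
    the Beaucage unified Guinier/power-law model and a bounded
    multi-start fitter for the radius of gyration and fractal exponent,
    multi-shell sphere form factors with a polydispersity-smeared
    shape-term negligibility check, the Porod invariant with Guinier and
    Porod tail extrapolation, X-ray scattering-length-density
    calculation, and the modified-invariant estimate of the volume
    fraction of polymer within a shell that occupies only part of the
    irradiated volume. Includes a synthetic-curve generator for
    parameter-recovery validation, plain-text curve file input/output
    with background subtraction and absolute calibration, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
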