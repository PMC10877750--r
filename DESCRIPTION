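Package: uvmix
Title: Resolution of Overlapped UV-Vis Spectra of Binary Drug Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Quantifies the components of binary mixtures from severely
    overlapped UV-Vis absorption spectra by three spectrophotometric
    procedures: dual wavelength (absorbance differences at a pair of
    wavelengths where the interferent contribution cancels), ratio
    difference (amplitude differences on the ratio spectrum obtained with
    a standard divisor), and first derivative of the ratio spectrum.
    Includes ICH-style calibration and validation statistics (linearity,
    recovery, precision, detection and quantitation limits, standard
    addition), pooled t and variance-ratio F comparison of assay methods
    from summary statistics, plasma dilution-chain arithmetic with matrix
    interference checks, a composite solvent greenness score, and a
    synthetic spectra generator so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
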