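Package: ringrelease
Title: In Vitro Release Testing Analysis for Matrix-Type Vaginal Rings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for in vitro release testing (IVRT) of
    matrix-type drug-releasing vaginal rings. Reconstructs per-interval and
    cumulative drug release from measured concentrations under monophasic
    (full medium replacement) and biphasic (buffer/octanol, partial sampling)
    protocols, including sampling-removal mass-balance corrections and HPLC
    calibration. Fits zero-order, Higuchi (root-time) and Korsmeyer-Peppas
    kinetic models with 95 percent confidence intervals, selects the time
    basis, classifies the release mechanism (partition- vs matrix-controlled,
    Fickian vs anomalous transport), assesses sink conditions against
    saturation solubility, and models weak-base physicochemistry (ionization,
    pH-dependent solubility, log D, Yasuda-Shedlovsky pKa extrapolation).
    Includes seeded forward simulators of both release protocols for
    validation and method development.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
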