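Package: gridtr
Title: Therapeutic Ratio Modelling for Spatially Fractionated (GRID)
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Radiobiological analysis of grid (spatially fractionated)
    radiotherapy delivered through perforated blocks. Generates
    parameterized single-hole radial dose profiles, derives
    linear-quadratic (LQ) cell-survival parameters from SF2 and the
    alpha/beta ratio, fits the three-parameter Hug-Kellerer high-dose
    survival model, computes survival fractions under non-uniform grid
    fields by circular-ring decomposition, solves the equivalent uniform
    dose (EUD), and evaluates the therapeutic ratio (TR) of a grid field
    relative to an open field at iso-tumour-effect. Includes
    EUD-matched sweeps over collimator hole diameter and centre-to-centre
    spacing, and bundled clinical grid-therapy response tables for
    correlating predicted TR and tumour radiosensitivity (SF2) with
    reported clinical response.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
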