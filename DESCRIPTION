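Package: braggfricke
Title: Track-End Radiolysis of the Super-Fricke Dosimeter Along Ion Bragg Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modelling of super-Fricke (ferrous sulfate)
    radiolysis along the track end of stopping proton and carbon-ion beams.
    Provides an analytic Bethe stopping-power engine with CSDA ranges,
    degrader transport and straggled Bragg energy-loss curves; the
    super-Fricke oxidation mechanism (rate constants, primary-yield
    combination, kinetic simulation); a forward simulator of a 20-fibre
    absorbance imager viewing sub-millimetre track segments; and the inverse
    pipeline that converts per-fibre absorbance time series into
    track-segment ferric-ion yields G(Fe3+) with Bragg-peak localisation,
    energy-loss-function alignment and shift-based uncertainty bands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
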