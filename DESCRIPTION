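Package: relpress
Title: Relative Pressure Estimation from 2D Velocity Fields with
    Pulsatile-Flow Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the pressure drop between two points from
    time-resolved 2D velocity fields (as produced by blood speckle imaging or
    echo particle image velocimetry) via the inviscid momentum balance
    integrated along a path, together with the verification layer such an
    estimator needs: analytic flow generators with closed-form pressure
    oracles, a Womersley pulsatile-tube benchmark solver with the pressure
    gradient recovered from a prescribed flow rate, a lumped-parameter model
    of a compliant flow phantom producing catheter-style pressure traces,
    Yeoh hyperelastic and Kelvin-Voigt constitutive models of tissue-mimicking
    gel, and the pulse segmentation / averaging / extrema protocol used to
    compare direct, image-based and simulated pressure drops.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
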