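Package: hfdialyzer
Title: Flow and Solute Transport in Hollow-Fiber Dialyzers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Axisymmetric modelling of counter-current hollow-fiber
    dialyzers at low blood and dialysate flow rates, as used in wearable
    artificial kidney (WAK) devices. Solves the steady Stokes-Brinkman
    equations for coupled lumen, porous-membrane and shell flow of a
    Krogh-cylinder fiber unit, and the convection-diffusion equation for
    small-solute transport with membrane retardation. Ultrafiltration
    follows Starling's law of filtration. Includes inverse calibration of
    the membrane hydraulic permeability against measured ultrafiltration
    and of solute diffusivities against measured port concentrations,
    dialysis performance metrics (trans-membrane pressure, ultrafiltration
    coefficient, generalized clearance, convective transfer fraction,
    dimensionless numbers), pulsatile pump waveform synthesis with a
    quasi-steadiness check, and a synthetic bench-case generator for
    parameter-recovery studies. Ships a bench characterization dataset
    for a Multiflow M60 dialyzer driven either by a counter-phased
    dual-ventricle pulsatile pump or by a roller/centrifugal pump pair.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
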