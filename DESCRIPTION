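Package: aortafit
Title: In Vivo Anisotropic Material Properties of the Ascending Aorta
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Non-invasive estimation of anisotropic hyperelastic material
    properties of the human ascending aorta from systolic and diastolic lumen
    perimeters. Implements a two-fiber-family anisotropic Mooney-Rivlin
    constitutive model, simulation and bounded least-squares fitting of planar
    biaxial tensile tests, a quasi-static inflation-extension forward model of
    an incompressible thick-walled tube, and a triple-loop inverse algorithm
    recovering the circumferential shrinkage ratio and a stiffness scale
    factor from cuff pressures and echocardiographic perimeters. Includes
    effective Young's moduli, an anisotropy index, exact one-sided Wilcoxon
    signed-rank statistics, and seeded generators for synthetic biaxial data
    and virtual subject cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
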