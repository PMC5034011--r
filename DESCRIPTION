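Package: plaquefuse
Title: Fusion of Fibrous-Cap Thickness and Wall Shear Stress for Coronary
    Plaque Risk Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies fibrous-cap thickness from intravascular optical
    coherence tomography (OCT) pullbacks with a dynamic-programming contour
    extractor in polar images, reconstructs a three-dimensional coronary
    lumen with elliptical cross-sections from two angiographic projections,
    computes wall shear stress on the reconstructed surface with a
    fully-developed elliptical-duct flow model (or imports external CFD
    samples), co-registers the two modalities axially and rotationally via
    side-branch landmarks, and fuses cap thickness and wall shear stress
    into a four-level plaque-vulnerability risk map with threshold
    sensitivity analysis. A parametric phantom generator produces synthetic
    vessels, biplane projections, OCT pullbacks and ground truth so the
    whole pipeline runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
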