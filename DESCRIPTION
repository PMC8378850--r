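Package: aerowave
Title: Self-Generated Oxygen Gradients and Collective Aerotactic Waves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Modeling and analysis stack for collective aerotactic migration of
    Dictyostelium discoideum colonies under self-generated oxygen gradients. A
    dense ring of cells forms at the edge of a vertically confined colony and
    travels outward at constant speed, guided by the oxygen gradient the cells
    themselves create by consumption. The package implements the coupled
    reaction-advection-diffusion mean-field model and the analytically solvable
    "Go or Grow" traveling-wave model (closed-form wave speed, pushed/pulled
    classification by neutral labeling, two-threshold variant solved by
    bisection), a 2-D cellular Potts simulator of the spot and microfluidic
    assays with oxygen-coupled aerotaxis, aerokinesis, consumption and division,
    the Stern-Volmer oxygen-sensor calibration pipeline, and the ring/track
    measurement operators (radial density profiles, Gaussian ring fits,
    kymographs, radial bias, per-track diffusion constants). Synthetic-data
    generators with known ground truth drive the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
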