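Package: ifp
Title: Intensity Field Projection for Online Adaptive Radiotherapy Replanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fast online replanning of intensity-modulated
    radiotherapy by intensity field projection (IFP). A three-dimensional
    deformation vector field relating the planning anatomy to the anatomy of
    the day is projected, beam by beam, into a two-dimensional deformation
    field on the isocenter plane using divergent-beam geometry; each beam's
    fluence map is warped along the projected field, re-fitted with jaw
    settings, and re-sequenced into step-and-shoot multi-leaf collimator
    segments. A synthetic thorax phantom generator with analytic ground-truth
    deformations, a simple primary-beam dose engine, and dose-volume histogram
    metrics allow the adapted plan to be compared against unadapted and
    rigid-repositioning strategies end to end without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
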