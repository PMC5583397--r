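Package: beatflow
Title: Optical-Flow Contractility Analysis of Beating Cardiomyocyte Monolayers
Version: 0.1.0
Authors@R:
    person("beatflow", "developers", email = "beatflow@example.org", role = c("aut", "cre"))
Description: Non-invasive quantification of cardiomyocyte contractility from
    label-free time-lapse microscopy. Estimates dense displacement fields by
    two-pass block-matching particle image velocimetry with thin-plate-spline
    denoising, extracts beat patterns and beat frequencies from the resulting
    motion traces, and converts displacement fields into noise-suppressed
    convergence (negative divergence) maps that localize actively contracting
    cell groups. Includes the closed-form and numerical solutions of an
    isotropic linear-elastic sheet with active contractile stress and elastic
    substrate drag, which serve as analytic oracles, and a ground-truth
    synthetic generator that renders beating-monolayer movies by warping
    seeded textures with the model's displacement fields.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
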