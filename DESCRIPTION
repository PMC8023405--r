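Package: morphorod
Title: Morphoelastic Rod Model of Growing, Circumnutating Plant Shoots
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a growing plant shoot as a three-dimensional
    morphoelastic Kirchhoff rod. Differential growth drives the intrinsic
    (spontaneous) curvatures through an endogenous oscillator, a delayed
    gravitropic response fed by statolith avalanche dynamics, and delayed
    proprioception; the visible shape follows from quasi-static elastic
    equilibrium under the shoot's own weight, with progressive stiffening
    by lignification. Includes a constant-length reduced model with tools
    to locate the onset of spontaneous oscillations (critical shoot length
    and critical growth time), a self-weight buckling normalization, and
    spectral classification of tip nutation patterns (pendular, elliptic,
    circular, trochoid-like).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
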