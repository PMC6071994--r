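Package: nscmigration
Title: Structure-Tensor Mapping and Stochastic Simulation of Neural Stem
    Cell Migration in Brain Histology
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies neural stem cell (NSC) migration in 2-D brain
    histology sections.  Computes per-pixel structure-tensor orientation
    and coherence maps of myelin-stained white matter, detects and
    coalesces NSC clusters to extract their tangent orientations,
    measures cluster-size-weighted distance distributions relative to an
    injection site and to the white/grey matter interface, correlates
    cluster orientation with local white-matter orientation by weighted
    axial regression, and simulates anisotropic NSC migration paths that
    follow the white-matter orientation field.  Includes a synthetic
    histology phantom generator with known ground truth for end-to-end
    validation, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
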