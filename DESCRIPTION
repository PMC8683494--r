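Package: ieegcover
Title: Probabilistic Gray and White Matter Coverage of Intracranial Electrodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies gray and white matter coverage of intracranial EEG
    electrodes (subdural strips and grids, penetrating depth leads) from
    probabilistic tissue segmentations. Coverage is modeled as the
    probability-weighted volume of the union of spherical radii of influence
    around contact centroids, swept across radii; subdural contacts are
    corrected for brain shift by projection onto a morphologically closed
    gray-matter surface; finite-element recording volumes derived from a
    tetrahedral head model provide a geometry-aware alternative compared to
    spheres via the Dice coefficient. Includes a synthetic gyrified phantom
    and electrode-layout generator so the full pipeline is testable without
    patient imaging, plus nonparametric group comparisons across implant
    modalities.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    RNifti,
    dplyr,
    tibble,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
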