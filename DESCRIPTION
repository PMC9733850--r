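Package: lamellaflex
Title: Mechanics and Order of Compressed Supported Lipid Multilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of supported lipid multilayer films under
    uniaxial compression on elastomer substrates. Implements the
    buckle-delamination mechanics model relating buckle width, film thickness
    and strain to the film-substrate adhesion energy, and its least-squares
    inversion with uncertainty; Lorentzian peak fitting of one-dimensional
    grazing-incidence scattering profiles with conversion of peak position and
    width to real-space spacings and correlation lengths; lipid director,
    tilt-angle, second-rank (P2) order-parameter and segmented inter-layer
    tilt-correlation statistics for coarse-grained multilayer configurations;
    topography roughness and buckle-geometry extraction; and seeded synthetic
    generators for every input the pipeline consumes (undulated multilayers,
    diffraction profiles, wrinkled height maps, buckle-geometry tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
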