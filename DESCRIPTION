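Package: glioswitch
Title: Hybrid Multiscale Simulation of Glioblastoma Go-or-Grow Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates post-surgical glioblastoma invasion and regrowth with a
    hybrid multiscale model: a bistable miR-451-AMPK-mTOR ordinary-differential
    switch inside each cell decides between migration and proliferation in
    response to local glucose, off-lattice force-based cell agents move, grow
    and divide under physical constraints, and continuum reaction-diffusion
    fields carry oxygen, glucose, chemoattractant, extracellular matrix,
    matrix-degrading proteinases and an intravenous chemotherapy drug.
    Includes steady-state and bifurcation analysis of the intracellular switch,
    scenario presets for vessel-density, chemoattractant-injection, drug-dose
    and tissue-stiffness sweeps, and trajectory/population metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
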