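Package: cordiff
Title: Quantitative Spinal Cord Diffusion MRI Microstructure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative microstructural analysis of cervical
    spinal cord diffusion MRI. Designs multi-shell gradient sampling
    schemes by electrostatic repulsion, simulates a segmented spinal-cord
    phantom with a three-compartment (ball-and-stick-and-stick) signal
    model and Rician noise, fits diffusion tensor and crossing-fiber
    models voxel-wise, extracts region-of-interest descriptive and
    kernel-density heuristic features including white-gray matter
    diffusivity gradients, estimates shell-wise signal-to-noise ratio and
    map-to-anatomy mutual information, and runs the group-difference,
    feature-selection, k-means classification and test-retest
    reproducibility cascade used to separate healthy controls from
    patients with non-myelopathic degenerative cervical cord compression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
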