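Package: sinusvol
Title: Deterministic Segmentation and Interval Volumetry of the Maxillary
    Sinus from Tomographic Slice Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based, training-free segmentation of the maxillary sinus
    from grayscale slice stacks (cone-beam computed tomography exports or
    8-bit image directories): global binarization with a user threshold,
    per-slice surface labelling under the L1 metric, seed-initiated
    propagation across planes with iterative forward/reverse refinement,
    and an erode-select-reconstruct procedure that severs thin apparent
    connections ("invisible septa") to neighbouring cavities. Volumes are
    reported as intervals: a lower bound from boundary removal, an upper
    bound from boundary addition, their midpoint as the estimate and half
    their width as the error, under a cubic-voxel model. Includes
    voxel-level agreement metrics (Cohen's kappa, Dice similarity,
    consensus union), paired pre/post cohort statistics with Student-t
    confidence intervals, and a seeded synthetic phantom generator with
    analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    RNifti,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
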