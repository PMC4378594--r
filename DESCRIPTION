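Package: odseg
Title: Optic Disc Segmentation from Color Fundus Images by a Texture-Driven Balloon Snake
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments the optic nerve head in color fundus photographs. The
    disc is localized by intensity template matching followed by a circle
    Hough transform, blood vessels are erased by harmonic (diffusion)
    inpainting over a vessel mask, rotation-invariant texture responses are
    computed with the Schmid and maximum-response (RFS/MR8) filter banks,
    texture noise from the cup boundary and residual vessel edges is
    suppressed by fuzzy c-means clustering with morphological cleanup, and the
    disc boundary is recovered by a balloon snake whose image force is the
    enhanced texture response rather than the intensity gradient, so the
    contour inflates from inside the disc and stops at the disc rim instead of
    the peripapillary atrophy. Includes a seeded generator of synthetic
    fundus-like images with ground-truth masks, baseline segmenters (gradient
    snake, texture clustering with ellipse fit), dice-coefficient evaluation,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
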