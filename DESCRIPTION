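Package: skewotsu
Title: Lognormal Between-Class Variance Thresholding for Right-Skewed Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automatic histogram thresholding for 8-bit grayscale images whose
    intensity histograms are skewed to the right, as is common in MRI
    brain-tumor slices and other biomedical images. Implements the classical
    Otsu between-class variance, a modified baseline that substitutes the
    lognormal (log-intensity) class means into Otsu's rational form, and a
    between-class variance computed entirely in log-intensity space, each with
    the exhaustive argmax threshold search. Ships a seeded generator of
    two-region images with lognormal mixture intensities and exact ground
    truth, supervised (Jaccard, F-score, accuracy) and unsupervised (image
    uniformity, region contrast) segmentation metrics, and a comparison
    pipeline that aggregates per-method averages and relative increase rates.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
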