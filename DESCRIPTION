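Package: slidealign
Title: Robust Rigid Co-Registration of Re-Stained Whole-Slide Image Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns pairs of whole-slide images (WSIs) of the same tissue
    section scanned after re-staining (for example hematoxylin & eosin
    followed by immunohistochemistry). Registration is rigid: image patches
    sampled from the low-resolution pyramid levels are registered by Fourier
    cross-power-spectrum phase correlation, the resulting per-patch offsets
    are weighted by a bivariate Gaussian kernel density estimate with a
    Scott's-rule bandwidth, and a weighted regression through the origin
    across pyramid levels extrapolates a precise full-resolution translation
    (and optional small rotation). Includes a synthetic re-stained pyramid
    generator with known ground truth for benchmarking, broom-style tidiers,
    ggplot2 diagnostics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
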