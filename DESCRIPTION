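Package: gliotex
Title: GLSZM Texture-Based Glioma Grading from Conventional MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades gliomas (low-grade vs high-grade) from two conventional
    MRI contrasts (post-contrast T1-weighted and T2-weighted) using gray level
    size zone matrix (GLSZM) texture features computed inside the necrotic and
    non-enhancing tumor core. Implements landmark-based (Nyul-style) intensity
    normalization to a common 0-255 scale, 3D GLSZM computation with
    26-connectivity and the thirteen standard zone-size features, an
    under-sampling ensemble that averages ordinary least-squares classifiers
    fitted on balanced training subsets after Wilcoxon rank-sum feature
    ranking, reduced-model search over variable subsets, and a published
    three-feature linear classifier ready for direct application. A synthetic
    cohort generator (labeled 3D volumes and ready-made feature tables) makes
    the full pipeline testable without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
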