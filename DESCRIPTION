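Package: owbfc
Title: Online Weighted Bayesian Fuzzy Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian fuzzy clustering via Metropolis-within-Gibbs maximum a
    posteriori inference, with per-sample weights and an online block-processing
    framework for data sets too large to cluster in one pass. Data are modelled
    with a fuzzy Gaussian likelihood whose per-cluster precision is the
    membership raised to a fuzzy index, a Dirichlet prior on membership rows and
    a Gaussian prior on cluster centers. The online variant partitions samples
    into blocks, clusters each block, pools the per-block centers as weighted
    representative points and consolidates them into the final centers. Includes
    the four external validity indices commonly reported for medical-data
    clustering (optimal-assignment accuracy, normalized cluster entropy,
    F-measure, purity), synthetic Gaussian-mixture and phantom-image generators,
    CSV and grayscale-image readers, and broom-style tidiers with ggplot2
    visualisations.
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
    png,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
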