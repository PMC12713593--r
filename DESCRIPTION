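Package: svgbias
Title: Flag Batch-Biased Genes in Spatially Variable Gene Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies genes in a candidate spatially-variable-gene (SVG)
    list whose apparent importance is driven by a batch variable (sample,
    slide, sex) rather than biology. Per-gene residual deviance under a
    binomial count model is computed with and without a categorical batch
    covariate; genes whose relative change in deviance (RCD) or deviance
    rank shift (RD) are outlying, on a standard-deviation (nSD) scale across
    the candidate set, are flagged and can be removed to refine the SVG list
    before downstream spatial clustering. Includes a multinomial count
    simulator with known batch-biased and spatially patterned genes for
    method validation, readers and writers for 10x-style MatrixMarket
    triplets and dense count tables, diagnostic scatterplots, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
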