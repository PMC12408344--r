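Package: fermentome
Title: Linking Cocoa Fermentation Kinetics to Chocolate Flavour and
    Designing Minimal Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing spontaneous cocoa-bean fermentations:
    fits a five-parameter generalized logistic model to temperature and pH
    time series and derives thirteen abiotic kinetic features; summarises
    taxon relative-abundance trajectories with seven growth-curve features;
    reduces redundant features by correlation clustering with
    coefficient-of-variation representative selection and quantifies
    feature-flavour associations by random-forest permutation importance
    (%IncMSE); and performs seed-based metabolic network expansion (scopes),
    computes the added value of metabolic cooperation, and enumerates minimal
    defined communities with metabolic capabilities equivalent to a full
    microbiome. A synthetic-data module generates every pipeline input with
    known ground truth so each stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
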