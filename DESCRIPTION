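Package: paddyghg
Title: Hydrologic Descriptors, Clustering and Greenhouse-Gas Accounting for
    Monsoon Rice Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the water regime of monsoon-season rice
    fields from daily water-tube records and linking it to seasonal methane and
    nitrous oxide emissions. Computes seventeen descriptors of flooding, drainage
    and saturation transitions from daily water-level series; groups fields into
    hydrologic clusters by K-means with silhouette-based selection of the number
    of clusters; derives soil hydraulic parameters from routine soil properties
    through published pedotransfer functions; converts seasonal fluxes to
    CO2-equivalents with AR6 GWP100 factors; classifies methane emission levels
    from hydrologic descriptors with random forests and a single classification
    tree; and runs nitrogen-rate by residue-retention sensitivity grids on
    cluster-representative fields. A synthetic-data module generates water-level
    series from parameterized hydrologic archetypes and seasonal emissions from
    a declared surrogate emission model, so the full pipeline is testable
    without field data or a process-based biogeochemistry model.
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
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
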