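Package: scalemorph
Title: Morphometric Delineation of Fossil Fish Scale Morphotypes and Squamation Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for delineating morphotypes of disarticulated
    rhombic fish scales from landmark-derived length variables. Computes
    inter-landmark length variables from 11-landmark crown-view
    configurations, prunes collinear variables by correlation, clusters
    scales by agglomerative hierarchical clustering (squared Euclidean
    distance, between-groups/average linkage, implemented from scratch),
    validates and refines the grouping by canonical variate analysis with
    Mahalanobis classification, summarises per-morphotype length and ratio
    statistics, and maps morphotypes onto a 4-belt/16-area squamation model
    of the body. Includes a synthetic-data generator that emulates the
    published per-morphotype means, standard deviations and group sizes so
    the whole pipeline is testable without the original measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
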