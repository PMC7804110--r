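Package: retgrid
Title: Location-Specific Cluster Analysis of Macular OCT Layer Thickness Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for location-specific normative analysis of macular optical
    coherence tomography (OCT) layer thickness measured on the fovea-centred
    8x8 Spectralis grid. Implements covariate screening of average layer
    thickness by backward step-wise elimination, spatial clustering of grid
    locations (within-groups hierarchical linkage and k-means) with a d-prime
    separability merge criterion, per-cluster quadratic age regression with
    vertex-age and post-vertex slope estimation, age-correction functions,
    ETDRS sector mapping, and coefficient-of-variation comparisons between
    grid-wise clusters and ETDRS sectors. A synthetic-cohort generator with
    known ground truth supports end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
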