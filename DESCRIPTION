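Package: coralflow
Title: Internal Skeletal Flow and Acidification Dissolution Modelling for
    Branching Corals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates seawater flow around and within voxelized skeletons of
    branching (Acropora-type) corals with a D3Q19 lattice-Boltzmann solver,
    generates synthetic coral-like labelled voxel volumes emulating micro-CT
    segmentations, post-processes flow fields into vorticity/enstrophy maps,
    streamline residence-time statistics, volume fluxes and
    upstream/downstream asymmetry tables, and projects aragonite dissolution
    under ocean acidification with an equivalent carbonate-tube
    transport-reaction model, including porosity-change and
    flexural-rigidity-loss estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
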