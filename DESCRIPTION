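Package: casanpp
Title: CASA Net Primary Productivity Estimation and Spatiotemporal Driver Analysis
Version: 0.1.0
Authors@R: person("NPP", "Tools", email = "npp@example.org", role = c("aut", "cre"))
Description: A raster pipeline for vegetation net primary productivity (NPP)
    analysis in the style used for arid-region remote-sensing studies:
    light-use-efficiency (CASA) NPP estimation from NDVI, solar radiation,
    temperature and precipitation; per-pixel linear-trend and Mann-Kendall
    significance mapping; NPP-weighted gravity-center migration; pixelwise
    second-order partial correlation of NPP with climate drivers; land-use
    transition accounting of NPP change; and an optimal-parameter geographic
    detector (q-statistic with data-driven scale, discretization method and
    bin count). A fully synthetic scenario generator with known, recoverable
    structure replaces downloaded satellite products so that every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
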