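Package: ncplinkr
Title: Species-to-NCP Relationship Tables and Per-Pixel Ecosystem-Service Indices
Version: 0.1.0
Authors@R: person("ncplinkr", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for building, validating and summarising signed species-by-NCP
    (Nature's Contributions to People) relationship matrices for tracheophyte and
    vertebrate assemblages: a packaged 17-NCP catalog derived from CICES V5.1,
    rule-based attribution (membership lists, evidence merging, third-quartile
    thresholding of reference counts), per-species and per-NCP aggregation with
    explicit NA semantics, a per-pixel NCP index on occurrence grids with
    plain-text raster export, synthetic-data generators with known ground truth,
    and a command-line pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    digest,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
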