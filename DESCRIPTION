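Package: floodepi
Title: Matched-Cohort Analysis of Flood Exposure and Hospitalisation Rates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating short- and medium-term changes in
    cause-specific hospitalisation rates during and after flood exposure
    using a self-matched design. Builds ZIP-day flood exposure flags from
    flood-map summaries, identifies consecutive-day exposure periods,
    matches each period to two non-flooded control windows in the same ZIP
    and days of the year, assembles a distributed-lag analytical dataset
    with person-time offsets and natural-spline confounder bases, and fits
    conditional quasi-Poisson distributed-lag models by profiled iteratively
    reweighted least squares. Includes stratified analyses (flood severity,
    season, admission type, ZIP-level demographics) and a synthetic-data
    generator with known injected lag effects for validation when restricted
    claims data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
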