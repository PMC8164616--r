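Package: aircrossover
Title: Time-Stratified Case-Crossover Analysis of Air Pollution and
    Daily Event Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying short-term associations between ambient
    air pollution and daily health-event counts (such as emergency
    department visits) with the time-stratified case-crossover design.
    Daily counts are modelled by conditional Poisson regression within
    year-month-weekday strata, with natural-spline adjustment for
    temperature and relative humidity and single-day exposure lags from
    0 to 14 days.  Includes construction of the Canadian Air Quality
    Health Index (AQHI and its 8-h ozone variant), daily maximum 8-h
    averaging of hourly series, enumeration of patient strata by sex,
    age group and season, aggregation of model results into binary and
    summed significance matrices, and a synthetic-data generator with
    planted effects for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
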