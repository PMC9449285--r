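Package: stepscape
Title: Daily Walking Step Estimation from Large-Scale GPS Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the spatial distribution of daily walking
    step counts from large-scale, irregularly sampled smartphone GPS logs.
    Reconstructs minute-resolution movement trajectories by straight-line
    interpolation, infers users' residence locations from daily first/last
    log clusters on the Japanese standardized grid-square (mesh code)
    system, computes daily land-use exposure via 100 m buffers over 100 m
    grid cells, links exposure to daily steps with a random-intercept
    generalized additive model, predicts fixed-effects step counts for
    users without step data, and aggregates predictions into 500 m
    residence-grid summaries by day type. Includes a synthetic-world
    generator emulating the quirks of commercial GPS data (duplicate
    minutes, accuracy noise, home-grid privacy masking) so the whole
    pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    lubridate,
    stringr,
    ggplot2,
    generics,
    mgcv,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
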