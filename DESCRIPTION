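Package: hingescan
Title: Canopy Plant Area Profiles from Hinge-Angle Scanning Lidar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fixed-position, almucantar-scanning ("hinge angle",
    57.5 degree zenith) rangefinding lidar used to monitor forest canopy
    structure. Converts full-azimuth scans to canopy gap probability,
    cumulative Plant Area Index (PAI) and Plant Area Volume Density (PAVD)
    profiles; screens rain- and wind-affected scans with run-length and
    summed-range quality filters; and aggregates daily profiles to monthly
    series with spline-fitted long-term trends. Includes the Campbell
    ellipsoidal leaf-angle-distribution projection and extinction
    coefficients, and a seeded Monte Carlo scan simulator with known
    ground truth (Beer-Lambert attenuation, detection-limit censoring,
    range quantization, rain-terminated and wind-perturbed scans) for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
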