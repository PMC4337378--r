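Package: fdpscan
Title: Food-Deprivation Periods and Movement Responses from GPS/ACC Biologging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers feeding events and food-deprivation periods (FDPs) of
    scavenging raptors from GPS tracks and accelerometer-classified
    behaviours, computes daily movement characteristics (travel distance,
    maximal displacement, straightness, roost-departure time, flight speed
    and elevation), and tests how movement responds to days since the last
    meal: constant/linear/quadratic model selection by AICc, paired
    hungry-versus-satiated contrasts with Benjamini-Yekutieli false
    discovery control, and a balanced two-way repeated-measures ANOVA
    contrasting short and long deprivation sequences. Includes a calibrated
    synthetic biologging generator emulating a supplementary-fed vulture
    population for validation and end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
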