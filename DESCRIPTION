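Package: shsjem
Title: Job Exposure Matrix Construction for Occupational Second-Hand Smoke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and analyses a job exposure matrix (JEM) for occupational
    second-hand tobacco smoke. Provides validation of multi-rater ordinal
    exposure ratings under a conditional likelihood/frequency/intensity
    scheme, Fleiss' kappa inter-rater agreement with disagreement
    localisation, consensus adjudication of conflicting ratings, a compound
    severity score, occupation-code crosswalk recoding of workforce counts,
    workforce-weighted exposure cross-tabulation, grouped socioeconomic
    summaries, and a seed-deterministic synthetic-data simulator for
    end-to-end testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
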