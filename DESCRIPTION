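Package: zahnreihen
Title: Tooth Replacement Wave Analysis for Polyphyodont Dentitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for analysing tooth replacement patterns in polyphyodont
    (continuously replacing) dentitions from per-tooth observational tables.
    Implements ordinal staging of functional and replacement teeth from wear
    and pulp-cavity features, reconstruction of Zahnreihen (caudally
    descending maturity runs), Z-spacing estimation with replacement-wave
    direction classification, regional and ontogenetic replacement-ratio
    summaries, a periodic replacement-wave simulator for parameter-recovery
    validation, and Zahnreihen graph plotting. Ships transcribed fixtures of
    published dentition tables for three Jurassic ceratopsians.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
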