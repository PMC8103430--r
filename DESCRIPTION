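Package: playscale
Title: Scoring and Reliability Analysis for the Children's Play Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for working with the Children's Play Scale (CPS), a
    parent-report questionnaire that measures where, how often, how long and
    how adventurously school-aged children play. Provides a documented
    tabular response schema with validation, configurable category-to-numeric
    mappings, the scoring algorithm that converts ordinal frequency and
    duration responses into annual hours of play and six headline metrics
    (total, outdoor, nature, adventurous-place and adventurous-play hours,
    plus mean adventure level), and the reliability statistics used to
    evaluate the instrument: Lin's concordance correlation coefficient with
    confidence intervals for cross-informant and test-retest agreement,
    Cronbach's alpha for internal consistency, and paired t-tests for
    stability across timepoints. A synthetic-data generator produces
    paired-informant, two-timepoint datasets with controllable latent
    agreement so the whole pipeline can be exercised and calibrated without
    access to real respondents.
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
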