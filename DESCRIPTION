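Package: sleepcomposites
Title: Infant Sleep Phenotyping from Ankle Actigraphy and 24-h Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Processes ankle actimetry and parent-completed 24-h diaries from
    longitudinal infant cohorts into a registry of 48 operationalised sleep
    variables (timing, duration, fragmentation, daytime sleep, regularity and
    day-to-day variability), screens recording days and assessments by
    family-specific validity rules, and reduces the variable set to five sleep
    composites (Sleep Activity, Sleep Timing, Sleep Night, Sleep Day, Sleep
    Variability) via principal component analysis with promax rotation.
    Includes multiple imputation by chained predictive mean matching, Rubin
    pooling, age/sex and developmental-outcome models, cross-timepoint
    stability analyses, and a fully synthetic longitudinal cohort generator
    driven by five correlated latent factors for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
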