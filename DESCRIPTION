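Package: burnyld
Title: Incidence-Based Non-Fatal Burden of Disease Estimation for Burn Injuries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives empirical disability weights from longitudinal EQ-5D-3L
    health-related quality of life data stratified by burn severity (%TBSA)
    and post-burn recovery window, classifies lifelong disability from
    two-year EQ-5D-3L profiles, and combines severity-grouped incidence data
    with disability weights, lifelong proportions and remaining life
    expectancy into incidence-based years lived with disability (YLD).
    Includes UK-tariff EQ-5D-3L utility scoring, generic crosswalk machinery
    for mapping other instruments onto EQ-5D-3L, a seeded synthetic cohort
    and incidence simulator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
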