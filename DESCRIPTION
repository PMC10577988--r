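Package: shoalmetrics
Title: Trajectory-Based Social Affinity, Locomotion, Sleep and Metabolic
    Phenotyping for Small Fish Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies social-like nearby interactions, turning bias,
    swimming distance, sleep bouts and vibration-attraction behavior from
    tracker-output X-Y coordinate tables of fish groups, with a
    permutation-calibrated chance criterion for sustained-proximity events.
    Includes a correlated-random-walk group simulator with tunable social
    attraction, speed modulation and two-state sleep dynamics for fixture
    generation and power studies, plus glucose-ketone-index computation,
    diet-mixture nutrient arithmetic and supplement dose conversions, and a
    group-comparison statistics layer with Holm step-down correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    emmeans,
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
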