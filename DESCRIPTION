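Package: olyprior
Title: Conservation-Aquaculture Prioritization of Olympia Oyster Estuaries
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A range-wide multi-criteria prioritization framework for
    conservation aquaculture of the Olympia oyster (Ostrea lurida). Per-estuary
    ordinal expert scores (0/1/2, optionally annotated with 1-3 certainty
    levels) on fourteen ecological and social criteria are combined into four
    weighted-sum indices (ecological priority, community restoration, community
    harvest, commercial production), normalized to [0,1] with exact rational
    threshold classification, veto (automatic-zero) criteria, and eligibility
    filtering on the three core ecological criteria. Includes score-table and
    configuration I/O with validation, ranking and tabular reporting,
    Monte-Carlo sensitivity analysis of priority-set stability under weight
    jitter, criterion removal and certainty-driven score resampling, and a
    synthetic score-table generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
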