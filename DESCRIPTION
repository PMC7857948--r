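Package: spcddi
Title: Empirical Filtering of Vitamin K Antagonist Drug-Drug Interaction Alerts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the empirical, data-driven filtering of drug-drug
    interaction (DDI) alert rules involving vitamin K antagonists (VKAs),
    by reuse of longitudinal inpatient electronic health records. The
    package reads daily drug-administration and laboratory tables, expands
    a DDI rulebook into initiation and discontinuation alert rules,
    constructs per-rule exposed and nonexposed observation windows, detects
    INR excursion outcomes (potentiation INR >= 5, inhibition INR <= 1.5),
    estimates unadjusted (Fisher exact conditional maximum likelihood),
    covariate-adjusted and stepwise-selected odds ratios per rule, and
    derives alert activation decisions in the style of a statistically
    prioritized and contextualized clinical decision support system.
    A seeded synthetic-EHR cohort generator with serialized ground truth
    supports calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
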