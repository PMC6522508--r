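Package: konosmeld
Title: MELD-Based Waitlist Stratification and Liver Allocation Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling deceased-donor liver allocation on the
    Korean waitlist: MELD score computation with KONOS capping and dialysis
    rules, classification under the previous CTP-based urgency statuses,
    Kaplan-Meier estimation and k-group log-rank testing implemented from
    first principles, survival-tree stratification of waitlist survival over
    MELD with a multiplicity-adjusted stopping rule, derivation of
    hepatocellular-carcinoma MELD exception points by survival equivalence,
    and queue ranking under the staged regional/national broader-sharing
    model. Includes a seeded synthetic-cohort generator calibrated to the
    published waitlist survival rates so every stage is testable without the
    original registry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), survival, jsonlite, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
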