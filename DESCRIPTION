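Package: adrmine
Title: Association Rule Mining for Spontaneous Adverse Drug Reaction Reports
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Pharmacovigilance signal exploration for JADER-style
    spontaneous-report databases. Reads DEMO/DRUG/REAC relational CSV
    tables, assembles per-case transactions, mines association rules with
    a level-wise apriori algorithm under support and confidence
    thresholds, computes support, confidence, lift and conviction from
    per-rule contingency tables (with explicit handling of the undefined
    conviction at confidence one), ranks adverse-reaction and
    demographics-to-gender rules into report tables, and generates
    synthetic JADER-like data with planted associations of known analytic
    strength for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
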