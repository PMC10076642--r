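Package: il17pv
Title: Pharmacovigilance Signal Detection for IL-17 Inhibitors and
    Inflammatory Bowel Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for disproportionality analysis of spontaneous
    adverse-event reports, built around the association between IL-17
    inhibitors (secukinumab, ixekizumab, brodalumab) and inflammatory
    bowel disease.  Reads FAERS-style quarterly ASCII tables, collapses
    duplicate case versions, matches brand and generic drug names,
    groups MedDRA preferred terms into event sets, and computes
    reporting odds ratios with Woolf 95% confidence intervals and a
    lower-bound signal rule.  Includes a descriptive summarizer for
    published case series, a seeded synthetic-report generator with
    planted drug-event odds ratios for parameter-recovery studies, and
    report writers that assemble the standard characteristics and
    disproportionality tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
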