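Package: dsmparse
Title: Rule-Based Extraction of DSM-IV-TR Autism Diagnostic Criteria from Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based parser that extracts expressions of the twelve
    DSM-IV-TR autistic-disorder diagnostic criteria (A1a-A3d) from free-text
    clinical records. Provides tokenization with coarse part-of-speech tags,
    scoped trigger-word lexicons with gazetteer lookup, a finite-state
    annotation-pattern engine with bounded gap arcs, a packaged starter
    ruleset, dual-level (annotation and sentence) evaluation against
    standoff gold annotations with partial-match semantics, a decision-tree
    sentence-classification baseline, a seeded synthetic electronic-health-
    record corpus generator with planted gold annotations, and longitudinal
    aggregation of extracted criteria by surveillance year and case status.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rpart,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
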