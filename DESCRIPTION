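Package: dvmh
Title: Rule-Based Extraction of Mental Health Disorder Mentions from
    Domestic Violence Police Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A knowledge-driven text-mining pipeline that detects mentions of
    mental health disorders in free-text domestic-violence police event
    narratives, attributes each mention to the person of interest (POI) or
    the victim via lexical pattern rules over hand-crafted gazetteers,
    standardizes noisy surface forms (misspellings, drug brand names),
    maps them into an extended four-level ICD-10 schema, deduplicates to
    narrative- and event-level unique records, and aggregates and evaluates
    the results (precision, recall, F-score, inter-annotator agreement).
    Ships a seeded synthetic-narrative generator with gold annotations so
    the whole pipeline is testable without access-restricted police data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
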