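Package: keeperllm
Title: Standardized Patient Profile Extraction and LLM Case Adjudication
    for Phenotype Algorithm Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Validates phenotype algorithms in OMOP Common Data Model data by
    extracting standardized, clinically organized patient profiles (KEEPER-style
    categories anchored to an index date), serializing them into staged chat
    prompts, adjudicating case status with a pluggable text-completion backend
    (including a deterministic offline mock and a recorded-replay backend), and
    estimating operating characteristics (sensitivity, specificity, AUC as the
    mean of the two, and PPV) against gold standards from majority-vote human
    review or large LLM-annotated silver standards, with exact binomial
    confidence intervals. Includes a seeded synthetic-data generator producing
    OMOP-shaped longitudinal coded events with planted case structure, so the
    whole pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
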