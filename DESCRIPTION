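Package: smisym
Title: Extraction of Severe Mental Illness Symptoms from Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A lexicon-driven pipeline for detecting symptoms of severe
    mental illness (SMI) in free-text clinical documents. Sentences
    containing symptom keywords (with optional or mandatory modifier terms
    within an eight-word window) become classifiable instances; a
    ConText-style rule engine assigns negation, experiencer and temporality;
    per-symptom linear support vector machines trained over bag-of-words and
    rule features, with a confidence-margin filter favouring precision,
    separate affirmed mentions from negated, hypothetical or irrelevant
    ones. Includes evaluation tooling (precision/recall/F1, Cohen's kappa),
    patient-level symptom profiling with ICD-10 diagnosis grouping, and a
    seeded synthetic discharge-summary generator with gold labels so the
    whole pipeline is testable without access to clinical records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
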