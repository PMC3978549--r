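Package: strokestory
Title: Mining Stroke Experience Narratives from Weblog Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale pipeline for infodemiology studies of stroke
    narratives told in weblogs. Provides a seeded synthetic corpus
    generator that plants first- and third-person stroke stories with
    gold symptom codes among non-medical distractors; a calibrated
    noise model and a trainable bag-of-words baseline for the personal
    story classifier that gates posts into the searchable index; a
    tf-idf vector-space index with cosine ranking and Rocchio relevance
    feedback driven by relevant/irrelevant/skip judgments; the
    traditional/nontraditional stroke symptom coding scheme with
    validation, inter-coder agreement, and a lexicon-based auto-coder;
    and contingency-table chi-square and logistic-regression analyses
    that reproduce published symptom tables from their printed counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
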