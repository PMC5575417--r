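Package: psychscreen
Title: Lexicon-Based Screening of Clinical Notes for Psychosocial Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens free-text clinical notes for psychosocial determinants of
    health using a curated 22-term lexicon spanning mental health, substance
    use, social determinants, and legal history. Candidate term mentions are
    filtered for negation, questionnaire/template boilerplate, polysemous
    abbreviations, and mentions attributed to family members rather than the
    patient. Patients are classified as high psychosocial risk when nine or
    more distinct lexicon terms survive filtering across their notes. Includes
    an interquartile-range non-overlap procedure for selecting discriminative
    terms between cohorts, contingency-table evaluation (accuracy, precision,
    recall, balanced F-measure), and a seeded synthetic note generator with
    gold-standard labels for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    stringr,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
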