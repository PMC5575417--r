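# psychscreen

Lexicon-based screening of free-text clinical notes for psychosocial
determinants of health.

Care coordination programs want to enroll patients whose risk is driven by
psychosocial factors — housing and food insecurity, mental illness,
substance use, legal history — but those factors rarely live in claims data
or structured EHR fields. They do appear in clinical notes. `psychscreen`
implements a word-recognition screener over notes for analysts and
informaticists building such enrollment pipelines:

* a curated **22-term lexicon** across four domains (mental health,
  substance use, social determinants, legal history), with per-term
  matching rules (prefix vs exact token, case sensitivity, collocates,
  exclusion cues);
* four **context filters** for the classic false-positive modes of naive
  string matching: negation ("not depressed"), questionnaire/template
  boilerplate (PHQ lines, checkboxes, repeated note text), polysemous
  abbreviations ("AA" as amino acid or demographic shorthand), and
  mentions describing a relative rather than the patient ("her son is in
  jail");
* a patient-level classifier: a patient is **high-risk when ≥ 9 distinct
  lexicon terms** have at least one affirmed mention across their notes —
  distinct categories, not raw counts, so one frequently documented
  problem cannot cross the line on volume;
* the **IQR non-overlap selection** procedure for choosing discriminative
  terms between an index and a control cohort: a candidate term is kept
  only when the interquartile intervals of its per-patient occurrence
  counts in the two cohorts are disjoint;
* **contingency-table evaluation** (accuracy, precision, recall, balanced
  F-measure, where F = 2PR/(P+R)) and a threshold sweep;
* a seeded **synthetic corpus generator** with exact gold-standard labels,
  so the whole pipeline is testable without patient data.

## Worked example

```r
library(psychscreen)

notes <- tibble::tibble(
  patient_id = c("mgh-001", "mgh-001", "mgh-002"),
  note_id    = c("n1", "n2", "n3"),
  date = NA_character_, note_type = "progress",
  text = c(
    paste("Pt currently homeless, staying in a shelter.",
          "Reports heroin and cocaine use; attends AA weekly.",
          "History of addiction, now intermittently sober.",
          "Applied for food stamps.", sep = "\n"),
    paste("Pt was in jail last year; reports ongoing anxiety.",
          "Appears depressed and angry with neurovegetative features.",
          "Tox positive on admission.", sep = "\n"),
    paste("Her son is in jail.",
          "PHQ-9 depression screen: [ ] yes [x] no",
          "Pt denies anxiety.",
          "African American AA male.", sep = "\n")))

res <- screen_notes(notes)
res
#> Screened 2 patients: 17 mentions (14 affirmed), 1 positive at threshold 9

res$tallies[, c("patient_id", "n_distinct", "risk")]
#>   patient_id n_distinct risk
#> 1 mgh-001            14 positive
#> 2 mgh-002             0 negative
```

Patient `mgh-001` has 14 distinct affirmed terms (homeless, shelter,
heroin, cocaine, aa, addict, sober, stamps, jail, anxiety, depressed,
angry, neurovegetative, tox) and is called positive at the ≥ 9 threshold.
Every candidate mention in `mgh-002`'s note is a false-positive scenario,
and each is caught by the matching filter:

```r
res$mentions[res$mentions$patient_id == "mgh-002",
             c("term_id", "matched_surface", "status")]
#>   term_id matched_surface status
#> 1 jail    jail            misallocated      (her *son* is in jail)
#> 2 anxiety anxiety         negated           (pt *denies* anxiety)
#> 3 aa      AA              polysemy_excluded (African American AA male)
```

(The `depression` token on the PHQ line is not even a candidate: the
lexicon term is `depressed`, exact-token.) Evaluating against gold labels:

```r
contingency(setNames(res$tallies$risk, res$tallies$patient_id),
            c("mgh-001" = "positive", "mgh-002" = "negative"))
#> Screening evaluation (2 patients)
#>   TP 1  FP 0  FN 0  TN 1
#>   accuracy  1.00 (100%)  precision 1.00 (100%)
#>   recall    1.00 (100%)  F-measure 1.00 (100%)
```

A thin command-line wrapper ships at `inst/cli/psychscreen` with
subcommands `screen`, `evaluate`, `select`, `simulate`, and `benchmark`,
reading JSONL notes, TSV lexicons, and CSV label files.

See `vignettes/screening-methods.Rmd` for the model, the filter defaults
and their rationale, the synthetic-data design, and known limitations.

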