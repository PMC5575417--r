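---
title: "Screening clinical notes for psychosocial risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening clinical notes for psychosocial risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Psychosocial determinants of health — housing and food insecurity, mental
health conditions, substance use, legal history — drive utilization in
high-risk patients but are poorly captured by claims data and structured EHR
fields. They do, however, surface in free-text clinical notes. `psychscreen`
implements a word-recognition screener over such notes: a small curated
lexicon, context filters for the classic false-positive modes of naive
string matching, and a patient-level decision rule suitable for screening a
census for care-coordination enrollment.

```{r}
library(psychscreen)
default_lexicon()
```

## The screening model

For each patient $p$ with notes $\mathcal{N}_p$, the screener computes the
set $T_p$ of distinct lexicon terms having at least one *affirmed* mention
anywhere in $\mathcal{N}_p$, and calls the patient high-risk when

$$|T_p| \ge \theta, \qquad \theta = 9 .$$

The decision statistic deliberately counts *categories* (distinct terms)
rather than raw mention counts: a patient whose sole problem is severe,
frequently documented anxiety, or a chart polluted by many copies of one
false-positive source, should not cross the line on volume alone. The
threshold of nine distinct terms is the algorithm's published operating
point and is exposed in `classifier_config()`.

A mention is *affirmed* when it survives four suppression filters, applied
in the fixed order **template → polysemy → negation → subject**; the first
filter to fire assigns the mention's status and the rest leave it alone.
The order puts the cheapest, most global evidence first (a boilerplate line
is template text regardless of its grammar) and makes composed outcomes
deterministic. Filters only ever change a mention's status — never its
term, span, or count — so suppression is monotone: disabling any filter can
only increase the number of affirmed mentions.

## The lexicon

The packaged lexicon has 22 terms in four domains. The published algorithm
specifies the surface strings; the per-term matching rules are this
package's reconstruction, documented here as deliberate choices:

* **Prefix matching** for `abuse`, `addict`, `sober`, `jail`, `homeless`,
  so "abused", "addiction", "sobriety", "jailed", and "homelessness" count.
  All other terms match whole tokens only — in particular `tox` does not
  match "toxicity", which in an oncology population is overwhelmingly
  chemotherapy toxicity, and `crack` does not match "cracked".
* **Case-sensitive `AA`**: the abbreviation for Alcoholics Anonymous is
  matched verbatim in upper case, with sentence-level exclusion cues
  (`amino`, `acid`, `african`, `american`) handled by the polysemy filter,
  since "AA" also appears as amino acid and demographic shorthand.
* **`stamps` requires "food"** within the two preceding tokens. The
  published term is the bare string; the collocate is a precision guard
  against postage.
* **Domain assignment** (mental health = anxiety, depressed, sad, angry,
  neurovegetative, schizoaffective; substance use = substance, abuse,
  addict, aa, sober, cocaine, heroin, crack, mushrooms, tox; legal history
  = prison, jail, stolen; social determinants = homeless, shelter, stamps)
  is an implementer mapping: the four domains are given but the per-term
  assignment is not, and `abuse` in particular could arguably sit in social
  determinants (child abuse). The mapping has no effect on scoring; it is
  metadata for reporting.

## Text processing

Tokenization splits on any non-alphanumeric character, keeping character
spans (0-based, half-open), so hyphenated compounds like "drug-abuse"
yield a matchable `abuse` token. Sentences end at `.`, `!`, `?`, `;`, or a
newline, with a guard list for common abbreviations ("Dr.", "etc.") and
for decimal points. Semicolons are treated as sentence boundaries because
clinical lists ("brother uses heroin; pt uses cocaine") scope negation and
attribution per clause. These conventions are a minimal reconstruction —
the upstream system's tokenizer is proprietary — and equivalence is claimed
only at the level of the documented scenarios.

## The four filters and their defaults

The false-positive scenarios named by the underlying algorithm are
negation, preformatted text, polysemy, and misallocation to a non-patient
subject. Trigger vocabularies, windows, and order are not published;
defaults here are deliberately small and conventional (in the spirit of
NegEx-style trigger lists), and everything is configurable through
`filter_config()`:

* **Negation**: triggers `no, not, denies, denied, without, never` plus the
  bigram `negative for`, looking up to 5 tokens *before* the term in the
  same sentence. Post-negation ("depressed: no") is left to the template
  filter's checkbox patterns; pre-negation dominates clinical phrasing.
* **Template**: a mention's line is boilerplate when it matches a marker
  (checkbox glyphs, `screen`, `questionnaire`, `PHQ`, `form`, "denies all
  of the following") or when the identical trimmed line occurs in at least
  5 distinct notes — a corpus-level repetition test that catches pasted
  templates no marker list anticipates.
* **Polysemy**: a rule's exclusion cues veto the mention anywhere in the
  same sentence. Only `aa` carries cues in the default lexicon.
* **Subject**: the cue list `son, daughter, mother, father, brother,
  sister, husband, wife, friend, family, partner, neighbor` within 5
  tokens before the term marks the mention as describing someone else.
  This is far short of full ConText-style experiencer resolution; it
  targets the dominant "her son is in jail" pattern.

Date-based recency filtering is deliberately absent: old text is carried
forward into new notes so freely that date parameters do more harm than
good, and the final published algorithm omitted them.

## Term selection by IQR non-overlap

`select_terms_by_iqr()` implements the candidate-screening procedure used
to cut a longer candidate list down to discriminative terms: for each term,
compute each patient's affirmed occurrence count, take the interquartile
interval $[Q_1, Q_3]$ in the index and control cohorts, and retain the term
only when the intervals are disjoint. Three numerical choices are ours:

* Quartiles use linear interpolation between order statistics
  (`stats::quantile` type 7, R's default), configurable via
  `quantile_type`.
* Touching endpoints (index $Q_1$ = control $Q_3$) count as overlap, the
  conservative reading: a term is only kept on strict separation.
* Selection uses raw per-patient occurrence counts ("the number of times
  each term was present"), while classification uses distinct-term counts;
  the two statistics serve different steps and are not interchangeable.

## The synthetic corpus generator

Real screening cohorts are protected patient data, so validation runs on
generated corpora with exact ground truth. `generate_corpus()` emulates the
statistical skeleton the screener assumes:

* index patients carry 9–22 distinct true terms, controls 0–8 (uniform),
  straddling the threshold by construction; each true term appears 1–5
  times in affirmed carrier sentences spread over 2–4 notes per patient;
* confounder sentences are injected per note at configurable rates, one
  generative template per false-positive mode: "pt denies X …" (negation),
  a PHQ-marked checkbox line (template), "her son uses X …" (subject), and
  a demographic "African American AA male" line (polysemy);
* every emitted mention — true or confounder — is recorded exactly once in
  the gold standard, and carrier sentences are screened so they contain no
  lexicon term other than the intended one;
* affirmed carrier lines embed a running visit number, which makes them
  line-unique so the boilerplate-repetition test cannot touch them: on a
  clean corpus the gold standard is exact by construction.

An optional `term_profile` gives per-term, per-group occurrence ranges,
which cohort-contrast experiments need (the burden fields alone cannot
express "ten terms differ between groups, five do not").

What the generator does *not* emulate: realistic clinical language,
section structure, copy-forward noise, misspellings, or correlated term
co-occurrence. Passing tests on synthetic corpora therefore demonstrate
the *mechanics* — matching, filtering, tallying, selection, evaluation —
not field performance on real charts; published cohort metrics (91%
accuracy, 80% precision, 98% recall) depend on protected patient data and
are not reproduction targets here.

Default confounder rates are 0.2 per note and mode, a moderate level
reflecting how common negation and templated text are in clinical notes;
validation scenarios set them explicitly (0 for clean corpora, swept over
0.1–0.5 for filter benchmarks).

## Evaluation

`contingency()` builds the patient-level 2×2 table against gold labels and
reports accuracy, precision, recall, and balanced F-measure
($F = 2PR/(P+R)$). Undefined ratios (no predicted positives, no gold
positives) are returned as `NA` with a warning, never silently zero.
`sweep_thresholds()` — a convenience extension beyond the core algorithm —
evaluates every threshold from 1 to 22.

## Problem sizes and determinism

Validation uses corpora of 200 patients (100 per group, 2–4 notes each),
which exercises every code path at comfortably interactive run times;
generation and screening are deterministic given the generator seed, and
the full pipeline (generate → screen → evaluate) is bit-reproducible,
which the test suite asserts on serialized outputs. Larger corpora change
nothing structurally — runtime grows linearly in total note text.

## Known limitations

* Negation looks backward only; "depression: none" survives unless a
  template marker catches the line.
* The subject filter has no window-free attachment logic: "pt, whose son
  is incarcerated, is homeless" correctly keeps `homeless` but would also
  keep a term more than five tokens after "son".
* Exact-token matching misses misspellings and morphological variants not
  covered by the five prefix rules.
* The lexicon is tuned to one care-coordination context; transplanting it
  to another population warrants re-running the IQR selection procedure on
  local cohorts.
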