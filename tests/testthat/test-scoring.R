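lex <- default_lexicon()

test_that("tallies count distinct categories, not raw mentions", {
  texts <- c(paste(rep("pt reports heroin use.", 7), collapse = "\n"),
             "pt currently homeless.")
  notes <- make_notes(texts)
  m <- apply_filters(find_candidates(notes, lex), notes, lex,
                     filter_config())
  tl <- tally_patients(m, notes, lex)
  expect_equal(tl$n_distinct, 2L)
  expect_setequal(tl$terms_present[[1]], c("heroin", "homeless"))
  expect_equal(unname(tl$occurrences[[1]]["heroin"]), 7L)

  # non-affirmed mentions are excluded entirely
  notes2 <- one_note("pt denies heroin use")
  m2 <- apply_filters(find_candidates(notes2, lex), notes2, lex,
                      filter_config())
  tl2 <- tally_patients(m2, notes2, lex)
  expect_equal(tl2$n_distinct, 0L)
  expect_equal(tl2$terms_present[[1]], character(0))

  # a patient with notes but no mentions still gets a zero tally
  notes3 <- make_notes(c("pt reports cocaine use", "routine visit"),
                       patient_ids = c("a", "b"))
  m3 <- find_candidates(notes3, lex)
  tl3 <- tally_patients(m3, notes3, lex)
  expect_equal(tl3$n_distinct[tl3$patient_id == "b"], 0L)

  # upper bound: one affirmed mention of each of the 22 terms
  tl4 <- make_tallies(list(p = stats::setNames(rep(1L, 22), lex$term_id)))
  expect_equal(tl4$n_distinct, 22L)
})

test_that("tally is invariant to how the text is split into notes", {
  sentences <- c("pt reports heroin use.", "now sober.",
                 "pt currently homeless.", "applied for food stamps.")
  one <- make_notes(paste(sentences, collapse = "\n"))
  four <- make_notes(sentences)
  cfg <- filter_config()
  t1 <- tally_patients(apply_filters(find_candidates(one, lex), one, lex,
                                     cfg), one, lex)
  t4 <- tally_patients(apply_filters(find_candidates(four, lex), four, lex,
                                     cfg), four, lex)
  expect_equal(t1$n_distinct, t4$n_distinct)
  expect_setequal(t1$terms_present[[1]], t4$terms_present[[1]])
})

test_that("classification applies the distinct-term threshold strictly", {
  mk <- function(n) make_tallies(list(
    p = stats::setNames(rep(1L, n), lex$term_id[seq_len(n)])))
  cfg9 <- classifier_config(9)
  expect_equal(classify_patients(mk(9), cfg9)$risk, "positive")
  expect_equal(classify_patients(mk(8), cfg9)$risk, "negative")
  for (th in c(1L, 9L, 22L)) {
    expect_equal(classify_patients(mk(22), classifier_config(th))$risk,
                 "positive")
  }
  # monotone: adding a term never flips positive -> negative
  for (n in 1:21) {
    r1 <- classify_patients(mk(n), cfg9)$risk
    r2 <- classify_patients(mk(n + 1), cfg9)$risk
    expect_false(r1 == "positive" && r2 == "negative")
  }
  expect_error(classifier_config(0), "threshold")
})

test_that("cohort summaries report mean, IQR, and range", {
  tl <- make_tallies(list(a = c(anxiety = 1L, sad = 1L),
                          b = c(anxiety = 1L, jail = 1L),
                          c = c(sad = 1L, jail = 1L, crack = 1L)))
  s <- summarize_cohort(tl, "true_negative_pediatric")
  expect_equal(s$mean, mean(c(2, 2, 3)), tolerance = 1e-12)
  expect_equal(round(s$mean, 2), 2.33)
  expect_equal(c(s$min, s$max), c(2, 3))

  s1 <- summarize_cohort(make_tallies(list(
    a = stats::setNames(rep(1L, 5), lex$term_id[1:5]))), "singleton")
  expect_equal(c(s1$mean, s1$q1, s1$q3, s1$min, s1$max), rep(5, 5))

  expect_error(summarize_cohort(make_tallies(list()), "empty"),
               "empty cohort")
})

test_that("cohort summary approaches the moments of the sampled law", {
  withr::with_seed(7, {
    vals <- sample(0:10, 1000, replace = TRUE)  # discrete uniform on 0..10
    tl <- make_tallies(stats::setNames(lapply(vals, function(v) {
      stats::setNames(rep(1L, v), lex$term_id[seq_len(v)])
    }), sprintf("p%04d", seq_along(vals))))
    s <- summarize_cohort(tl, "sim")
    expect_equal(s$mean, 5, tolerance = 0.1)   # E = 5, se ~ 0.1
    expect_equal(s$q1, 2.5, tolerance = 1)
    expect_equal(s$q3, 7.5, tolerance = 1)
    expect_equal(c(s$min, s$max), c(0, 10))
  })
})

test_that("per-term occurrence quartiles match the quantile oracle", {
  tl <- make_tallies(list(a = c(tox = 0L)[0], b = c(tox = 0L)[0],
                          c = c(tox = 1L), d = c(tox = 3L)))
  st <- term_occurrence_stats(tl, "tox", "index")
  expect_equal(st$counts[[1]], c(0L, 0L, 1L, 3L))
  expect_equal(st$q1, 0)
  expect_equal(st$q3, 1.5)
  expect_equal(unname(stats::quantile(c(0, 0, 1, 3), c(.25, .75), type = 7)),
               c(st$q1, st$q3))

  # all-zero and singleton samples
  z <- term_occurrence_stats(make_tallies(list(a = c(sad = 0L)[0],
                                               b = c(sad = 0L)[0])),
                             "sad", "g")
  expect_equal(c(z$q1, z$q3), c(0, 0))
  one <- term_occurrence_stats(make_tallies(list(a = c(sad = 4L))), "sad",
                               "g")
  expect_equal(c(one$q1, one$q3), c(4, 4))
})

test_that("IQR selection keeps exactly the terms with disjoint intervals", {
  mk_cohort <- function(counts_by_patient) make_tallies(counts_by_patient)
  # index counts of "heroin" in {3..6}, control in {0..1}: disjoint
  idx <- mk_cohort(lapply(c(3, 4, 5, 6), function(k) c(heroin = k)))
  ctl <- mk_cohort(list(a = c(heroin = 0L)[0], b = c(heroin = 1L),
                        c = c(heroin = 1L), d = c(heroin = 0L)[0]))
  sel <- select_terms_by_iqr(lex, idx, ctl)
  expect_true(sel$retained[sel$term_id == "heroin"])
  # all other terms are identically zero in both cohorts: overlap, dropped
  expect_false(any(sel$retained[sel$term_id != "heroin"]))

  # overlapping IQR intervals: index [2,5] vs control [4,7]
  idx2 <- mk_cohort(lapply(c(2, 2, 5, 5), function(k) c(sad = k)))
  ctl2 <- mk_cohort(lapply(c(4, 4, 7, 7), function(k) c(sad = k)))
  sel2 <- select_terms_by_iqr(lex, idx2, ctl2)
  expect_false(sel2$retained[sel2$term_id == "sad"])

  # touching endpoints count as overlap (conservative)
  idx3 <- mk_cohort(lapply(c(2, 2, 2, 2), function(k) c(jail = k)))
  ctl3 <- mk_cohort(lapply(c(0, 1, 2, 2), function(k) c(jail = k)))
  sel3 <- select_terms_by_iqr(lex, idx3, ctl3)
  expect_false(sel3$retained[sel3$term_id == "jail"])

  # symmetry under swapping cohort labels
  sel_swapped <- select_terms_by_iqr(lex, ctl, idx)
  expect_equal(sel_swapped$retained, sel$retained)

  expect_error(select_terms_by_iqr(lex, idx[0, ], ctl), "nonempty")
})
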