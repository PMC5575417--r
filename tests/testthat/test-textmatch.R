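test_that("read_notes parses JSONL and enforces uniqueness", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"patient_id":"p1","note_id":"n1","text":"pt stable"}',
    '{"patient_id":"p1","note_id":"n2","date":"2016-03-01","text":"f/u"}',
    '{"patient_id":"p2","note_id":"n1","note_type":"ed","text":"seen"}'),
    path)
  notes <- read_notes(path)
  expect_equal(nrow(notes), 3L)
  expect_equal(notes$date[2], "2016-03-01")
  expect_equal(notes$note_type[3], "ed")

  writeLines(character(0), path)
  expect_equal(nrow(read_notes(path)), 0L)

  writeLines(c(
    '{"patient_id":"p1","note_id":"n1","text":"a"}',
    '{"patient_id":"p1","note_id":"n1","text":"b"}'), path)
  expect_error(read_notes(path), "duplicate")

  writeLines('{"patient_id": "p1", not json', path)
  expect_error(read_notes(path), "line 1")
})

test_that("notes round-trip through JSONL", {
  notes <- make_notes(c("pt is well.", "line one\nline two"),
                      patient_ids = c("a", "b"))
  notes$date[1] <- "2016-01-02"
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_notes(notes, path)
  expect_equal(as.data.frame(read_notes(path)), as.data.frame(notes))
})

test_that("sentence segmentation handles clause breaks and abbreviations", {
  s <- segment_sentences("Pt is homeless. Denies cocaine use.")
  expect_equal(nrow(s), 2L)
  expect_equal(s$text, c("Pt is homeless.", "Denies cocaine use."))

  expect_equal(nrow(segment_sentences("")), 0L)
  expect_equal(nrow(segment_sentences("   \n ")), 0L)

  # abbreviation guard and decimal guard
  expect_equal(nrow(segment_sentences("Dr. Smith saw pt")), 1L)
  expect_equal(nrow(segment_sentences("K was 3.5 today")), 1L)

  # semicolons and newlines break sentences
  expect_equal(nrow(segment_sentences("brother uses heroin; pt uses cocaine")),
               2L)
  expect_equal(nrow(segment_sentences("line one\nline two")), 2L)
})

test_that("sentence spans tile the non-whitespace text", {
  texts <- c("Pt is homeless. Denies cocaine use.",
             "Dr. Smith saw pt!  Was it so? yes.\nnew line; more",
             "one",
             "a. b. c. d.")
  for (tx in texts) {
    s <- segment_sentences(tx)
    covered <- rep(FALSE, nchar(tx))
    for (i in seq_len(nrow(s))) {
      expect_true(s$start[i] >= 0 && s$end[i] <= nchar(tx))
      if (i > 1) expect_true(s$start[i] >= s$end[i - 1])  # ordered, disjoint
      covered[(s$start[i] + 1):s$end[i]] <- TRUE
    }
    nonws <- gregexpr("\\S", tx)[[1]]
    expect_true(all(covered[nonws]))
  }
})

test_that("tokenization splits on non-alphanumerics and keeps spans", {
  tk <- tokenize_text("drug-abuse, noted (severe)")
  expect_equal(tk$token, c("drug", "abuse", "noted", "severe"))
  expect_equal(substr("drug-abuse, noted (severe)", tk$start[2] + 1,
                      tk$end[2]), "abuse")
  expect_equal(nrow(tokenize_text("")), 0L)
})

test_that("candidate detection matches the documented rule semantics", {
  lex <- default_lexicon()

  m <- find_candidates(one_note("pt admits heroin and cocaine use"), lex)
  expect_setequal(m$term_id, c("heroin", "cocaine"))

  m <- find_candidates(one_note("history of addiction; now sober"), lex)
  expect_setequal(m$term_id, c("addict", "sober"))
  expect_setequal(m$matched_surface, c("addiction", "sober"))

  # exact-case abbreviation plus case-rule miss
  expect_equal(find_candidates(one_note("AA meeting tonight"), lex)$term_id,
               "aa")
  expect_equal(nrow(find_candidates(one_note("aa amino acid profile"), lex)),
               0L)

  # exact_token does not fire on longer words
  expect_equal(nrow(find_candidates(
    one_note("chemotherapy toxicity noted; cracked rib"), lex)), 0L)

  # collocate: "stamps" needs a preceding "food" within two tokens
  expect_equal(find_candidates(one_note("applied for food stamps"),
                               lex)$term_id, "stamps")
  expect_equal(nrow(find_candidates(one_note("collects postage stamps"),
                                    lex)), 0L)
  expect_equal(nrow(find_candidates(
    one_note("food was good but stamps missing"), lex)), 0L)

  # all fresh candidates are affirmed, ordered by offset
  m <- find_candidates(one_note("homeless pt, heroin use, now in jail"), lex)
  expect_true(all(m$status == "affirmed"))
  expect_true(!is.unsorted(m$start))
})

test_that("mention spans point at the matched surface and stay in-sentence", {
  lex <- default_lexicon()
  tx <- "Pt was depressed. Later: heroin relapse.\nNow sober, in a shelter."
  note <- one_note(tx)
  m <- find_candidates(note, lex)
  sents <- segment_sentences(tx)
  for (i in seq_len(nrow(m))) {
    expect_equal(substr(tx, m$start[i] + 1, m$end[i]), m$matched_surface[i])
    srow <- sents[sents$sentence_idx == m$sentence_idx[i], ]
    expect_true(m$start[i] >= srow$start && m$end[i] <= srow$end)
  }
})

test_that("matcher agrees with a brute-force token-scan oracle", {
  lex <- default_lexicon()
  vocab <- matcher_vocab(lex)
  withr::with_seed(42, {
    for (rep in 1:40) {
      tokens <- sample(vocab, sample(3:25, 1), replace = TRUE)
      text <- paste(tokens, collapse = " ")
      got <- find_candidates(one_note(text), lex)
      want <- oracle_match_tokens(tokens, lex)
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$term_id, want$term_id[order(want$position,
                                                   want$term_id)])
      expect_equal(got$token_idx, sort(want$position))
    }
  })
})

test_that("matching is idempotent and insensitive to note order", {
  lex <- default_lexicon()
  notes <- make_notes(c("pt uses heroin daily", "now sober and in shelter"),
                      patient_ids = c("p1", "p2"))
  m1 <- find_candidates(notes, lex)
  m2 <- find_candidates(notes[2:1, ], lex)
  key <- function(m) m[order(m$patient_id, m$note_id, m$start),
                       c("patient_id", "term_id", "start")]
  expect_equal(key(m1), key(m2), ignore_attr = TRUE)
  expect_equal(find_candidates(notes, lex), m1)
})
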