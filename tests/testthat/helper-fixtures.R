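# Shared fixture builders and independent oracles.

make_notes <- function(texts, patient_ids = NULL, note_ids = NULL) {
  n <- length(texts)
  tibble::tibble(
    patient_id = patient_ids %||% rep("p1", n),
    note_id = note_ids %||% sprintf("n%d", seq_len(n)),
    date = NA_character_, note_type = NA_character_,
    text = texts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

one_note <- function(text, patient_id = "p1", note_id = "n1") {
  make_notes(text, patient_id, note_id)
}

# Tallies built directly (bypassing text), for scoring-level tests:
# `occ_list` is a named list patient_id -> named integer vector of per-term
# affirmed counts.
make_tallies <- function(occ_list) {
  if (is.null(names(occ_list)) && length(occ_list) > 0) {
    names(occ_list) <- sprintf("p%d", seq_along(occ_list))
  }
  if (length(occ_list) == 0) {
    return(tibble::tibble(patient_id = character(), n_distinct = integer(),
                          terms_present = list(), occurrences = list()))
  }
  tibble::tibble(
    patient_id = names(occ_list),
    n_distinct = unname(vapply(occ_list, function(x) sum(x >= 1L),
                               integer(1))),
    terms_present = unname(lapply(occ_list, function(x) names(x)[x >= 1L])),
    occurrences = unname(lapply(occ_list, function(x) x[x >= 1L])))
}

# Independent brute-force matcher oracle: scan every token of a one-sentence
# text against every rule, re-deriving the matching semantics from scratch.
oracle_match_tokens <- function(tokens, lexicon) {
  hits <- list()
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    for (r in seq_len(nrow(lexicon))) {
      pat <- lexicon$pattern[r]
      a <- tok
      b <- pat
      if (lexicon$case_mode[r] == "insensitive") {
        a <- tolower(a)
        b <- tolower(b)
      }
      ok <- if (lexicon$match_mode[r] == "exact_token") {
        identical(a, b)
      } else {
        nchar(a) >= nchar(b) && identical(substr(a, 1, nchar(b)), b)
      }
      if (ok && !is.na(lexicon$collocate_token[r])) {
        lo <- max(1, i - lexicon$collocate_dist[r])
        prev <- if (i == 1) character(0) else tokens[lo:(i - 1)]
        ok <- lexicon$collocate_token[r] %in% tolower(prev)
      }
      if (ok) {
        hits[[length(hits) + 1]] <-
          data.frame(position = i, term_id = lexicon$term_id[r])
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(position = integer(), term_id = character()))
  }
  do.call(rbind, hits)
}

# Vocabulary for random token sequences: lexicon surfaces, inflected
# variants, decoys that share prefixes, and neutral filler.
matcher_vocab <- function(lexicon) {
  c(lexicon$pattern, "addiction", "abused", "sobriety", "jailed",
    "homelessness", "toxicity", "AA", "aa", "Aa", "crackers", "sadly",
    "substances", "prisoner", "food", "the", "patient", "was", "with",
    "chronic", "pain", "visit", "note", "stable")
}
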