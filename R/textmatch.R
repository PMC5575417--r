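# Abbreviations whose trailing period does not end a sentence.
SENTENCE_ABBREV <- c("dr", "mr", "mrs", "ms", "st", "jr", "sr", "vs",
                     "etc", "eg", "ie", "al", "approx")

#' Read clinical notes from a JSON-lines file
#'
#' One JSON object per line with keys `patient_id`, `note_id`, optional
#' `date` (ISO-8601) and `note_type`, and `text`. Records with empty ids or
#' duplicate `(patient_id, note_id)` pairs are rejected.
#'
#' @param path path to the JSONL file.
#' @return A tibble with columns `patient_id`, `note_id`, `date`,
#'   `note_type`, `text`.
#' @export
read_notes <- function(path) {
  if (!file.exists(path)) {
    stop("notes file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_notes())
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) {
                      stop("malformed JSON at line ", i, " of ", path, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    recs[[i]] <- tibble::tibble(
      patient_id = as.character(rec$patient_id %||% ""),
      note_id = as.character(rec$note_id %||% ""),
      date = as.character(rec$date %||% NA_character_),
      note_type = as.character(rec$note_type %||% NA_character_),
      text = as.character(rec$text %||% "")
    )
  }
  notes <- dplyr::bind_rows(recs)
  validate_notes(notes)
  notes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_notes <- function() {
  tibble::tibble(patient_id = character(), note_id = character(),
                 date = character(), note_type = character(),
                 text = character())
}

validate_notes <- function(notes) {
  if (any(!nzchar(notes$patient_id)) || any(!nzchar(notes$note_id))) {
    stop("patient_id and note_id must be nonempty", call. = FALSE)
  }
  key <- paste(notes$patient_id, notes$note_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, note_id): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  invisible(notes)
}

#' Write clinical notes to a JSON-lines file
#'
#' @param notes a notes tibble as returned by [read_notes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_notes <- function(notes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    rec <- list(patient_id = notes$patient_id[i], note_id = notes$note_id[i])
    if (!is.na(notes$date[i])) rec$date <- notes$date[i]
    if (!is.na(notes$note_type[i])) rec$note_type <- notes$note_type[i]
    rec$text <- notes$text[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, sep = "\n")
  }
  invisible(path)
}

#' Split note text into sentences
#'
#' Sentences end at `.`, `!`, `?`, `;`, or a newline. A period preceded by a
#' common abbreviation ("Dr.", "etc.") or sitting between two digits does not
#' end a sentence. Spans are 0-based half-open character offsets into the
#' original text, trimmed of surrounding whitespace; whitespace-only chunks
#' are dropped.
#'
#' @param text a single character string.
#' @return Tibble with `sentence_idx` (0-based), `start`, `end` (0-based
#'   half-open), and `text`.
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- tibble::tibble(sentence_idx = integer(), start = integer(),
                          end = integer(), text = character())
  n <- nchar(text)
  if (is.na(text) || n == 0) return(empty)

  hits <- stringr::str_locate_all(text, "[.!?;\n]")[[1]]
  pos <- hits[, 1]
  if (length(pos) > 0) {
    ch <- substring(text, pos, pos)
    keep <- vapply(seq_along(pos), function(i) {
      if (ch[i] != ".") return(TRUE)
      p <- pos[i]
      before <- substr(text, max(1, p - 20), p - 1)
      after <- if (p < n) substr(text, p + 1, p + 1) else ""
      # decimal number: digit on both sides
      if (grepl("[0-9]$", before) && grepl("^[0-9]", after)) return(FALSE)
      word <- stringr::str_extract(before, "[A-Za-z]+$")
      !(!is.na(word) && tolower(word) %in% SENTENCE_ABBREV)
    }, logical(1))
    pos <- pos[keep]
  }
  ends <- unique(c(pos, n))
  starts <- c(1L, utils::head(ends, -1) + 1L)

  out <- vector("list", length(starts))
  k <- 0L
  for (i in seq_along(starts)) {
    chunk <- substr(text, starts[i], ends[i])
    m <- gregexpr("\\S", chunk)[[1]]
    if (m[1] == -1) next
    s1 <- starts[i] + m[1] - 1L            # 1-based first non-space
    e1 <- starts[i] + m[length(m)] - 1L    # 1-based last non-space
    k <- k + 1L
    out[[k]] <- tibble::tibble(sentence_idx = k - 1L, start = s1 - 1L,
                               end = e1, text = substr(text, s1, e1))
  }
  if (k == 0) return(empty)
  dplyr::bind_rows(out[seq_len(k)])
}

#' Tokenize text into alphanumeric tokens with character spans
#'
#' Tokens are maximal runs of ASCII letters and digits; everything else
#' (including hyphens, so "drug-abuse" yields tokens "drug" and "abuse") is a
#' separator. Spans are 0-based half-open offsets into `text`.
#'
#' @param text a single character string.
#' @return Tibble with `token`, `start`, `end`.
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(token = character(), start = integer(),
                          end = integer()))
  }
  loc <- stringr::str_locate_all(text, "[A-Za-z0-9]+")[[1]]
  tibble::tibble(token = substring(text, loc[, 1], loc[, 2]),
                 start = as.integer(loc[, 1] - 1L),
                 end = as.integer(loc[, 2]))
}

# Full annotation of one note text: sentences, per-sentence tokens with
# absolute spans, and newline-delimited lines. All spans 0-based half-open.
annotate_text <- function(text) {
  sents <- segment_sentences(text)
  if (nrow(sents) == 0) {
    tokens <- tibble::tibble(sentence_idx = integer(), token_idx = integer(),
                             token = character(), start = integer(),
                             end = integer())
  } else {
    tokens <- purrr::map2(sents$text, seq_len(nrow(sents)), function(st, i) {
      tk <- tokenize_text(st)
      tk$start <- tk$start + sents$start[i]
      tk$end <- tk$end + sents$start[i]
      tk$sentence_idx <- sents$sentence_idx[i]
      tk$token_idx <- seq_len(nrow(tk))
      tk
    })
    tokens <- dplyr::bind_rows(tokens)[, c("sentence_idx", "token_idx",
                                           "token", "start", "end")]
  }
  lines <- line_table(text)
  list(sentences = sents, tokens = tokens, lines = lines)
}

# Newline-delimited lines of a text with 0-based half-open spans.
line_table <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(line_idx = integer(), start = integer(),
                          end = integer(), text = character()))
  }
  parts <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(parts) == 0) parts <- ""
  lens <- nchar(parts)
  start <- cumsum(c(0L, utils::head(lens + 1L, -1)))
  tibble::tibble(line_idx = seq_along(parts) - 1L, start = start,
                 end = start + lens, text = parts)
}

#' Find candidate lexicon mentions in notes
#'
#' Scans every token of every note against every lexicon rule. A rule hits a
#' token when the token equals the pattern (`exact_token`) or starts with it
#' (`prefix_token`), after case folding unless `case_mode = "exact"`, and any
#' collocate constraint is satisfied by a preceding token within the stated
#' distance in the same sentence. One mention is produced per (rule, token)
#' hit; all fresh mentions have status `"affirmed"` until a context filter
#' reassigns them (see [apply_filters()]).
#'
#' @param notes a notes tibble (one or more rows).
#' @param lexicon a `psychscreen_lexicon`.
#' @return Mentions tibble: `patient_id`, `note_id`, `term_id`,
#'   `sentence_idx` (0-based), `token_idx` (1-based within sentence),
#'   `start`, `end` (0-based half-open into the note text),
#'   `matched_surface`, `line_idx`, `line`, `status`; ordered by note and
#'   character offset.
#' @export
find_candidates <- function(notes, lexicon) {
  validate_notes(notes)
  res <- vector("list", nrow(notes))
  for (i in seq_len(nrow(notes))) {
    ann <- annotate_text(notes$text[i])
    res[[i]] <- match_tokens(ann, lexicon, notes$patient_id[i],
                             notes$note_id[i])
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) return(empty_mentions())
  out
}

empty_mentions <- function() {
  tibble::tibble(patient_id = character(), note_id = character(),
                 term_id = character(), sentence_idx = integer(),
                 token_idx = integer(), start = integer(), end = integer(),
                 matched_surface = character(), line_idx = integer(),
                 line = character(), status = character())
}

match_tokens <- function(ann, lexicon, patient_id, note_id) {
  tk <- ann$tokens
  if (nrow(tk) == 0) return(empty_mentions())
  tk_lower <- tolower(tk$token)
  hits <- vector("list", nrow(lexicon))
  for (r in seq_len(nrow(lexicon))) {
    pat <- lexicon$pattern[r]
    fold <- lexicon$case_mode[r] == "insensitive"
    tok <- if (fold) tk_lower else tk$token
    pat_cmp <- if (fold) tolower(pat) else pat
    idx <- if (lexicon$match_mode[r] == "exact_token") {
      which(tok == pat_cmp)
    } else {
      which(startsWith(tok, pat_cmp))
    }
    if (length(idx) == 0) next
    if (!is.na(lexicon$collocate_token[r])) {
      ctok <- lexicon$collocate_token[r]
      cdist <- lexicon$collocate_dist[r]
      ok <- vapply(idx, function(j) {
        prev <- which(tk$sentence_idx == tk$sentence_idx[j] &
                        tk$token_idx >= tk$token_idx[j] - cdist &
                        tk$token_idx < tk$token_idx[j])
        any(tk_lower[prev] == ctok)
      }, logical(1))
      idx <- idx[ok]
    }
    if (length(idx) == 0) next
    hits[[r]] <- tibble::tibble(
      patient_id = patient_id, note_id = note_id,
      term_id = lexicon$term_id[r],
      sentence_idx = tk$sentence_idx[idx], token_idx = tk$token_idx[idx],
      start = tk$start[idx], end = tk$end[idx],
      matched_surface = tk$token[idx]
    )
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) return(empty_mentions())
  # attach line index/text from the mention's character offset
  li <- findInterval(out$start, ann$lines$start)
  out$line_idx <- ann$lines$line_idx[li]
  out$line <- ann$lines$text[li]
  out$status <- "affirmed"
  out[order(out$start, out$term_id), ]
}
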