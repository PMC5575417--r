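FILTER_NAMES <- c("template", "polysemy", "negation", "subject")

#' Configuration for the false-positive suppression filters
#'
#' Four filters address the classic false-positive sources in naive lexicon
#' matching over clinical text: negated statements ("not depressed"),
#' questionnaire/template boilerplate, polysemous abbreviations ("AA" as
#' amino acid or demographic shorthand), and mentions describing a relative
#' or friend rather than the patient.
#'
#' @param negation_triggers tokens (or space-separated token bigrams such as
#'   `"negative for"`) that negate a following term.
#' @param negation_window maximum number of tokens between trigger and term,
#'   same sentence, trigger before term.
#' @param subject_cues tokens indicating a non-patient experiencer.
#' @param subject_window maximum tokens between cue and term, cue before
#'   term, same sentence.
#' @param template_markers case-insensitive regular expressions; a mention
#'   whose newline-delimited line matches any of them is template text.
#' @param template_min_notes a line occurring verbatim in at least this many
#'   distinct notes is treated as boilerplate even without a marker.
#' @param enabled_filters subset of `c("template", "polysemy", "negation",
#'   "subject")`.
#' @return A `psychscreen_filter_config` list.
#' @export
filter_config <- function(negation_triggers = c("no", "not", "denies",
                                                "denied", "without", "never",
                                                "negative for"),
                          negation_window = 5L,
                          subject_cues = c("son", "daughter", "mother",
                                           "father", "brother", "sister",
                                           "husband", "wife", "friend",
                                           "family", "partner", "neighbor"),
                          subject_window = 5L,
                          template_markers = c("\\[\\s*[xX]?\\s*\\]",
                                               "screen", "questionnaire",
                                               "PHQ", "form",
                                               "denies all of the following"),
                          template_min_notes = 5L,
                          enabled_filters = FILTER_NAMES) {
  negation_window <- as.integer(negation_window)
  subject_window <- as.integer(subject_window)
  template_min_notes <- as.integer(template_min_notes)
  stopifnot(negation_window >= 1L, subject_window >= 1L,
            template_min_notes >= 1L)
  bad <- setdiff(enabled_filters, FILTER_NAMES)
  if (length(bad) > 0) {
    stop("unknown filter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(negation_triggers = tolower(negation_triggers),
                 negation_window = negation_window,
                 subject_cues = tolower(subject_cues),
                 subject_window = subject_window,
                 template_markers = template_markers,
                 template_min_notes = template_min_notes,
                 enabled_filters = enabled_filters),
            class = "psychscreen_filter_config")
}

# Annotations for each note, keyed by "patient\rnote".
note_annotations <- function(notes) {
  anns <- lapply(seq_len(nrow(notes)), function(i) {
    annotate_text(notes$text[i])
  })
  names(anns) <- paste(notes$patient_id, notes$note_id, sep = "\r")
  anns
}

mention_keys <- function(mentions) {
  paste(mentions$patient_id, mentions$note_id, sep = "\r")
}

# TRUE where a cue token (or multiword cue) occurs within `window` tokens
# before the mention's token in the same sentence.
preceding_cue_fires <- function(mentions, anns, cues, window) {
  cue_words <- strsplit(cues, " ", fixed = TRUE)
  keys <- mention_keys(mentions)
  vapply(seq_len(nrow(mentions)), function(m) {
    tk <- anns[[keys[m]]]$tokens
    sent <- tk[tk$sentence_idx == mentions$sentence_idx[m], ]
    low <- tolower(sent$token)
    i <- mentions$token_idx[m]
    win <- seq.int(max(1L, i - window), i - 1L)
    if (i == 1L) return(FALSE)
    for (cw in cue_words) {
      k <- length(cw)
      for (j in win) {
        if (j + k - 1L >= i || j + k - 1L > length(low)) next
        if (all(low[j:(j + k - 1L)] == cw)) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
}

template_fires <- function(mentions, line_counts, cfg) {
  line_trim <- trimws(mentions$line)
  marker_hit <- rep(FALSE, nrow(mentions))
  for (mk in cfg$template_markers) {
    marker_hit <- marker_hit |
      stringr::str_detect(mentions$line, stringr::regex(mk, ignore_case = TRUE))
  }
  rep_hit <- !is.na(match(line_trim, names(line_counts))) &
    line_counts[line_trim] >= cfg$template_min_notes
  rep_hit[is.na(rep_hit)] <- FALSE
  marker_hit | as.logical(rep_hit)
}

# Number of distinct notes in which each trimmed nonempty line occurs.
corpus_line_counts <- function(notes) {
  if (nrow(notes) == 0) return(integer(0))
  per_note <- lapply(seq_len(nrow(notes)), function(i) {
    ln <- unique(trimws(strsplit(notes$text[i], "\n", fixed = TRUE)[[1]]))
    ln[nzchar(ln)]
  })
  tab <- table(unlist(per_note))
  stats::setNames(as.integer(tab), names(tab))
}

polysemy_fires <- function(mentions, anns, lexicon) {
  cue_map <- stats::setNames(lexicon$cues, lexicon$term_id)
  keys <- mention_keys(mentions)
  vapply(seq_len(nrow(mentions)), function(m) {
    cues <- cue_map[[mentions$term_id[m]]]
    if (is.null(cues) || length(cues) == 0) return(FALSE)
    tk <- anns[[keys[m]]]$tokens
    low <- tolower(tk$token[tk$sentence_idx == mentions$sentence_idx[m]])
    any(low %in% cues)
  }, logical(1))
}

apply_status <- function(mentions, fires, new_status) {
  hit <- mentions$status == "affirmed" & fires
  mentions$status[hit] <- new_status
  mentions
}

#' Mark mentions negated by a preceding trigger
#'
#' A mention becomes `"negated"` when a negation trigger occurs within
#' `negation_window` tokens before it in the same sentence. Only
#' currently-affirmed mentions are touched.
#'
#' @param mentions a mentions tibble from [find_candidates()].
#' @param notes the notes the mentions came from.
#' @param cfg a [filter_config()].
#' @return The mentions tibble with updated `status`.
#' @export
filter_negation <- function(mentions, notes, cfg = filter_config()) {
  if (nrow(mentions) == 0) return(mentions)
  anns <- note_annotations(notes)
  fires <- preceding_cue_fires(mentions, anns, cfg$negation_triggers,
                               cfg$negation_window)
  apply_status(mentions, fires, "negated")
}

#' Mark mentions inside questionnaire or boilerplate lines
#'
#' A mention becomes `"templated"` when its newline-delimited line matches a
#' template marker (checkbox glyphs, "screen", "questionnaire", "PHQ", ...)
#' or when the identical trimmed line occurs in at least
#' `template_min_notes` distinct notes of the corpus.
#'
#' @inheritParams filter_negation
#' @return The mentions tibble with updated `status`.
#' @export
filter_template <- function(mentions, notes, cfg = filter_config()) {
  if (nrow(mentions) == 0) return(mentions)
  fires <- template_fires(mentions, corpus_line_counts(notes), cfg)
  apply_status(mentions, fires, "templated")
}

#' Mark polysemous mentions vetoed by an exclusion cue
#'
#' A mention becomes `"polysemy_excluded"` when any of its rule's
#' `exclusion_cues` occurs in the same sentence (e.g. "AA" near "amino
#' acid" or "African American").
#'
#' @inheritParams filter_negation
#' @param lexicon the lexicon the mentions were matched against.
#' @return The mentions tibble with updated `status`.
#' @export
filter_polysemy <- function(mentions, notes, lexicon) {
  if (nrow(mentions) == 0) return(mentions)
  anns <- note_annotations(notes)
  fires <- polysemy_fires(mentions, anns, lexicon)
  apply_status(mentions, fires, "polysemy_excluded")
}

#' Mark mentions attributed to a relative or friend
#'
#' A mention becomes `"misallocated"` when a non-patient subject cue ("son",
#' "mother", "friend", ...) occurs within `subject_window` tokens before it
#' in the same sentence; semicolons act as sentence boundaries, so "brother
#' uses heroin; pt uses cocaine" misallocates only the first clause.
#'
#' @inheritParams filter_negation
#' @return The mentions tibble with updated `status`.
#' @export
filter_subject <- function(mentions, notes, cfg = filter_config()) {
  if (nrow(mentions) == 0) return(mentions)
  anns <- note_annotations(notes)
  fires <- preceding_cue_fires(mentions, anns, cfg$subject_cues,
                               cfg$subject_window)
  apply_status(mentions, fires, "misallocated")
}

#' Apply all enabled suppression filters in fixed order
#'
#' Filters run template, then polysemy, then negation, then subject; the
#' first filter to fire sets the mention's status and later filters leave it
#' alone. Mentions that survive every enabled filter remain `"affirmed"`.
#' Filters never change a mention's term or span, only its status, and the
#' number of mentions is conserved.
#'
#' @inheritParams filter_negation
#' @param lexicon the lexicon the mentions were matched against.
#' @return The mentions tibble with final statuses.
#' @export
apply_filters <- function(mentions, notes, lexicon, cfg = filter_config()) {
  if (nrow(mentions) == 0) return(mentions)
  enabled <- cfg$enabled_filters
  if (length(enabled) == 0) return(mentions)
  anns <- note_annotations(notes)
  if ("template" %in% enabled) {
    fires <- template_fires(mentions, corpus_line_counts(notes), cfg)
    mentions <- apply_status(mentions, fires, "templated")
  }
  if ("polysemy" %in% enabled) {
    fires <- polysemy_fires(mentions, anns, lexicon)
    mentions <- apply_status(mentions, fires, "polysemy_excluded")
  }
  if ("negation" %in% enabled) {
    fires <- preceding_cue_fires(mentions, anns, cfg$negation_triggers,
                                 cfg$negation_window)
    mentions <- apply_status(mentions, fires, "negated")
  }
  if ("subject" %in% enabled) {
    fires <- preceding_cue_fires(mentions, anns, cfg$subject_cues,
                                 cfg$subject_window)
    mentions <- apply_status(mentions, fires, "misallocated")
  }
  mentions
}
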