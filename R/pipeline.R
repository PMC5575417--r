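#' Screen a corpus of notes end to end
#'
#' Runs the full pipeline: candidate matching against the lexicon, context
#' filtering (template, polysemy, negation, subject attribution), patient
#' level distinct-term tallying, and threshold classification.
#'
#' @param notes a notes tibble ([read_notes()]).
#' @param lexicon a `psychscreen_lexicon` (default: packaged 22-term).
#' @param filter_cfg a [filter_config()].
#' @param classifier_cfg a [classifier_config()].
#' @return A `psychscreen_screen` list: `mentions` (with statuses),
#'   `tallies` (with `risk` calls), and the configs used.
#' @export
screen_notes <- function(notes, lexicon = default_lexicon(),
                         filter_cfg = filter_config(),
                         classifier_cfg = classifier_config()) {
  mentions <- find_candidates(notes, lexicon)
  mentions <- apply_filters(mentions, notes, lexicon, filter_cfg)
  tallies <- tally_patients(mentions, notes, lexicon)
  tallies <- classify_patients(tallies, classifier_cfg)
  structure(list(mentions = mentions, tallies = tallies,
                 lexicon = lexicon, filter_cfg = filter_cfg,
                 classifier_cfg = classifier_cfg),
            class = "psychscreen_screen")
}

#' @export
print.psychscreen_screen <- function(x, ...) {
  n_aff <- sum(x$mentions$status == "affirmed")
  cat(sprintf(paste0("Screened %d patients: %d mentions (%d affirmed), ",
                     "%d positive at threshold %d\n"),
              nrow(x$tallies), nrow(x$mentions), n_aff,
              sum(x$tallies$risk == "positive"), x$classifier_cfg$threshold))
  invisible(x)
}

# Flatten tallies for CSV output.
tallies_to_csv_table <- function(tallies) {
  tibble::tibble(
    patient_id = tallies$patient_id,
    n_distinct = tallies$n_distinct,
    terms_present = vapply(tallies$terms_present, paste,
                           character(1), collapse = ","),
    classification = tallies$risk)
}
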