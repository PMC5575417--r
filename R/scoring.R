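#' Classifier configuration
#'
#' The decision statistic is the number of *distinct* lexicon terms with at
#' least one affirmed mention across all of a patient's notes — categories,
#' not raw term counts, so one frequently-documented problem (or one
#' recurring false-positive source) cannot by itself push a patient over the
#' line. A patient is called positive when that count reaches `threshold`
#' (default 9).
#'
#' @param threshold minimum distinct-term count for a positive call; at
#'   least 1.
#' @return A `psychscreen_classifier_config` list.
#' @export
classifier_config <- function(threshold = 9L) {
  threshold <- as.integer(threshold)
  stopifnot(length(threshold) == 1, !is.na(threshold), threshold >= 1L)
  structure(list(threshold = threshold),
            class = "psychscreen_classifier_config")
}

#' Aggregate filtered mentions into per-patient tallies
#'
#' Counts only mentions whose status is `"affirmed"`. Every patient present
#' in `notes` receives a tally, including patients with no affirmed
#' mentions (`n_distinct = 0`).
#'
#' @param mentions filtered mentions (statuses assigned).
#' @param notes the notes tibble defining the patient universe.
#' @param lexicon the lexicon used for matching (bounds `n_distinct`).
#' @return Tibble with `patient_id`, `n_distinct`, list-columns
#'   `terms_present` (character vector of distinct terms) and `occurrences`
#'   (named integer vector of affirmed mention counts per term).
#' @export
tally_patients <- function(mentions, notes, lexicon) {
  patients <- unique(notes$patient_id)
  aff <- mentions[mentions$status == "affirmed", , drop = FALSE]
  tallies <- lapply(patients, function(p) {
    mm <- aff[aff$patient_id == p, , drop = FALSE]
    occ <- table(mm$term_id)
    occ <- stats::setNames(as.integer(occ), names(occ) %||% character(0))
    occ <- occ[order(names(occ))]
    tibble::tibble(patient_id = p, n_distinct = length(occ),
                   terms_present = list(names(occ)),
                   occurrences = list(occ))
  })
  out <- dplyr::bind_rows(tallies)
  if (nrow(out) == 0) {
    out <- tibble::tibble(patient_id = character(), n_distinct = integer(),
                          terms_present = list(), occurrences = list())
  }
  stopifnot(all(out$n_distinct <= nrow(lexicon)))
  out
}

#' Classify patients by distinct-term count
#'
#' @param tallies output of [tally_patients()].
#' @param cfg a [classifier_config()].
#' @return `tallies` with a `risk` column, `"positive"` when
#'   `n_distinct >= threshold`, else `"negative"`.
#' @export
classify_patients <- function(tallies, cfg = classifier_config()) {
  tallies$risk <- ifelse(tallies$n_distinct >= cfg$threshold,
                         "positive", "negative")
  tallies
}

#' Summarize a cohort's distinct-term burden
#'
#' Mean, interquartile range, and range of `n_distinct` across patients.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7) unless another type is requested.
#'
#' @param tallies per-patient tallies for one cohort.
#' @param group label for the cohort.
#' @param quantile_type passed to [stats::quantile()].
#' @return One-row tibble: `group`, `n`, `mean`, `q1`, `q3`, `min`, `max`.
#' @export
summarize_cohort <- function(tallies, group, quantile_type = 7) {
  if (nrow(tallies) == 0) stop("empty cohort: ", group, call. = FALSE)
  v <- tallies$n_distinct
  q <- stats::quantile(v, c(0.25, 0.75), type = quantile_type, names = FALSE)
  tibble::tibble(group = group, n = length(v), mean = mean(v),
                 q1 = q[1], q3 = q[2], min = min(v), max = max(v))
}

# Per-patient affirmed occurrence count of one term (0 when absent).
term_counts <- function(tallies, term_id) {
  unname(vapply(tallies$occurrences, function(occ) {
    n <- occ[term_id]
    if (is.na(n)) 0L else as.integer(n)
  }, integer(1)))
}

#' Occurrence statistics of one term within a cohort
#'
#' Per-patient affirmed mention counts of the term (0 for patients without
#' it), with the 25th and 75th percentiles.
#'
#' @inheritParams summarize_cohort
#' @param term_id the lexicon term.
#' @return One-row tibble: `term_id`, `group`, list-column `counts`, `q1`,
#'   `q3`.
#' @export
term_occurrence_stats <- function(tallies, term_id, group,
                                  quantile_type = 7) {
  if (nrow(tallies) == 0) stop("empty cohort: ", group, call. = FALSE)
  counts <- term_counts(tallies, term_id)
  q <- stats::quantile(counts, c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  tibble::tibble(term_id = term_id, group = group, counts = list(counts),
                 q1 = q[1], q3 = q[2])
}

#' Select discriminative terms by interquartile-range non-overlap
#'
#' For each candidate term, the per-patient occurrence counts in the index
#' and control cohorts are reduced to their interquartile intervals
#' \[Q1, Q3\]. A term is retained only when the two intervals are disjoint;
#' touching endpoints count as overlap (conservative), so a term whose index
#' Q1 equals the control Q3 is dropped. Selection uses raw per-patient
#' occurrence counts; the classifier itself uses distinct-term counts.
#'
#' @param lexicon candidate lexicon.
#' @param index_tallies tallies for the index (high-risk) cohort.
#' @param control_tallies tallies for the control cohort.
#' @param quantile_type passed to [stats::quantile()].
#' @return Tibble with one row per candidate term: `term_id`, `index_q1`,
#'   `index_q3`, `control_q1`, `control_q3`, `retained`.
#' @export
select_terms_by_iqr <- function(lexicon, index_tallies, control_tallies,
                                quantile_type = 7) {
  if (nrow(index_tallies) == 0 || nrow(control_tallies) == 0) {
    stop("both cohorts must be nonempty", call. = FALSE)
  }
  rows <- lapply(lexicon$term_id, function(tid) {
    iq <- stats::quantile(term_counts(index_tallies, tid), c(0.25, 0.75),
                          type = quantile_type, names = FALSE)
    cq <- stats::quantile(term_counts(control_tallies, tid), c(0.25, 0.75),
                          type = quantile_type, names = FALSE)
    disjoint <- iq[1] > cq[2] || cq[1] > iq[2]
    tibble::tibble(term_id = tid, index_q1 = iq[1], index_q3 = iq[2],
                   control_q1 = cq[1], control_q3 = cq[2],
                   retained = disjoint)
  })
  dplyr::bind_rows(rows)
}
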