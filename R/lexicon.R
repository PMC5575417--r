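MATCH_MODES <- c("exact_token", "prefix_token")
CASE_MODES <- c("insensitive", "exact")
DOMAINS <- c("mental_health", "substance_use", "social_determinants",
             "legal_history")

#' Construct a validated lexicon
#'
#' A lexicon is a tibble of term rules with class `psychscreen_lexicon`.
#' Each rule describes one surface pattern to look for in note text:
#'
#' * `term_id` — canonical lowercase label, unique within the lexicon.
#' * `pattern` — surface form to match against a single token.
#' * `match_mode` — `"exact_token"` (full-token equality) or `"prefix_token"`
#'   (the token merely starts with the pattern, so `"jailed"` matches
#'   pattern `"jail"`).
#' * `case_mode` — `"insensitive"` (default folding) or `"exact"` (verbatim,
#'   used for abbreviations such as `"AA"`).
#' * `domain` — one of the four psychosocial domains: mental health,
#'   substance use, social determinants, legal history.
#' * `collocate` — optional required preceding token with a maximum token
#'   distance, written `"token:distance"` (e.g. `"food:2"` for `stamps`).
#' * `exclusion_cues` — optional comma-separated context tokens that veto a
#'   hit when present in the same sentence (the polysemy filter).
#'
#' @param rules data frame with the columns above (`collocate` and
#'   `exclusion_cues` may be `NA` or empty strings when absent).
#' @param name label for the lexicon.
#' @param version version string.
#' @return A `psychscreen_lexicon` tibble with parsed
#'   `collocate_token`/`collocate_dist` and list-column `cues`.
#' @export
as_lexicon <- function(rules, name = "custom", version = "1") {
  rules <- tibble::as_tibble(rules)
  required <- c("term_id", "pattern", "match_mode", "case_mode", "domain")
  missing_cols <- setdiff(required, names(rules))
  if (length(missing_cols) > 0) {
    stop("lexicon is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"collocate" %in% names(rules)) rules$collocate <- NA_character_
  if (!"exclusion_cues" %in% names(rules)) rules$exclusion_cues <- NA_character_
  rules$collocate <- blank_to_na(as.character(rules$collocate))
  rules$exclusion_cues <- blank_to_na(as.character(rules$exclusion_cues))

  dup <- rules$term_id[duplicated(rules$term_id)]
  if (length(dup) > 0) {
    stop("duplicate term_id in lexicon: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_mode <- setdiff(unique(rules$match_mode), MATCH_MODES)
  if (length(bad_mode) > 0) {
    stop("unknown match_mode: ", paste(bad_mode, collapse = ", "),
         call. = FALSE)
  }
  bad_case <- setdiff(unique(rules$case_mode), CASE_MODES)
  if (length(bad_case) > 0) {
    stop("unknown case_mode: ", paste(bad_case, collapse = ", "),
         call. = FALSE)
  }
  bad_dom <- setdiff(unique(rules$domain), DOMAINS)
  if (length(bad_dom) > 0) {
    stop("unknown domain: ", paste(bad_dom, collapse = ", "), call. = FALSE)
  }

  colloc <- parse_collocates(rules$collocate)
  rules$collocate_token <- colloc$token
  rules$collocate_dist <- colloc$dist
  rules$cues <- parse_cues(rules$exclusion_cues)

  structure(rules,
            class = c("psychscreen_lexicon", class(tibble::tibble())),
            lexicon_name = name, lexicon_version = version)
}

blank_to_na <- function(x) {
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  x
}

parse_collocates <- function(x) {
  token <- rep(NA_character_, length(x))
  dist <- rep(NA_integer_, length(x))
  has <- !is.na(x)
  if (any(has)) {
    parts <- strsplit(x[has], ":", fixed = TRUE)
    ok <- vapply(parts, length, integer(1)) == 2L
    if (!all(ok)) {
      stop("malformed collocate (expected 'token:distance'): ",
           paste(x[has][!ok], collapse = ", "), call. = FALSE)
    }
    token[has] <- tolower(vapply(parts, `[[`, character(1), 1L))
    d <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
    if (anyNA(d) || any(d < 1L)) {
      stop("collocate distance must be a positive integer", call. = FALSE)
    }
    dist[has] <- d
  }
  list(token = token, dist = dist)
}

parse_cues <- function(x) {
  lapply(x, function(v) {
    if (is.na(v)) character(0)
    else tolower(trimws(strsplit(v, ",", fixed = TRUE)[[1]]))
  })
}

#' Load a lexicon from a tab-separated file
#'
#' Expects a header row with columns `term_id`, `pattern`, `match_mode`,
#' `case_mode`, `domain`, `collocate`, `exclusion_cues`; empty string or
#' missing value means the optional field is absent. Duplicate `term_id`s and
#' values outside the match/case/domain enumerations are rejected.
#'
#' @param path path to the TSV file.
#' @inheritParams as_lexicon
#' @return A `psychscreen_lexicon`.
#' @export
load_lexicon <- function(path, name = basename(path), version = "1") {
  if (!file.exists(path)) {
    stop("lexicon file not found: ", path, call. = FALSE)
  }
  rules <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  probs <- readr::problems(rules)
  if (nrow(probs) > 0) {
    stop("malformed lexicon row at line ", probs$row[1], " of ", path,
         call. = FALSE)
  }
  as_lexicon(rules, name = name, version = version)
}

#' Write a lexicon to a tab-separated file
#'
#' Inverse of [load_lexicon()]: reloading the written file yields an
#' identical lexicon.
#'
#' @param lexicon a `psychscreen_lexicon`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  out <- lexicon[, c("term_id", "pattern", "match_mode", "case_mode",
                     "domain", "collocate", "exclusion_cues")]
  out$collocate[is.na(out$collocate)] <- ""
  out$exclusion_cues[is.na(out$exclusion_cues)] <- ""
  readr::write_tsv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' The packaged 22-term psychosocial risk lexicon
#'
#' The default lexicon covers four psychosocial domains: mental health
#' (anxiety, depressed, sad, angry, neurovegetative, schizoaffective),
#' substance use (substance, abuse, addict, aa, sober, cocaine, heroin,
#' crack, mushrooms, tox), legal history (prison, jail, stolen), and social
#' determinants (homeless, shelter, stamps). Five terms match as prefixes
#' (`abuse`, `addict`, `sober`, `jail`, `homeless`) so inflected forms such
#' as "addiction" or "homelessness" count; `aa` matches only the verbatim
#' uppercase "AA" and is vetoed near amino-acid or demographic context;
#' `stamps` requires a preceding "food" within two tokens; `tox` is an exact
#' token so chemotherapy "toxicity" does not match.
#'
#' @return A `psychscreen_lexicon` with exactly 22 rules.
#' @export
default_lexicon <- function() {
  path <- system.file("extdata", "psychosocial_lexicon_22.tsv",
                      package = "psychscreen", mustWork = TRUE)
  load_lexicon(path, name = "psychosocial-22", version = "1")
}

#' @export
print.psychscreen_lexicon <- function(x, ...) {
  cat(sprintf("<lexicon '%s' v%s: %d terms>\n",
              attr(x, "lexicon_name"), attr(x, "lexicon_version"), nrow(x)))
  NextMethod()
}
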