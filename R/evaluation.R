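#' Balanced F-measure
#'
#' Harmonic mean of precision and recall (beta = 1):
#' `2 * P * R / (P + R)`. Returns `NA` with a warning when both inputs are
#' zero.
#'
#' @param precision,recall proportions in \[0, 1\].
#' @return The balanced F-measure, or `NA` when undefined.
#' @export
f_measure <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) {
    warning("F-measure undefined: precision and recall are both zero")
    return(NA_real_)
  }
  2 * precision * recall / (precision + recall)
}

#' Contingency-table evaluation of predicted vs gold labels
#'
#' Builds the 2x2 table of true/false positives/negatives over patients and
#' derives accuracy, precision, recall, and balanced F-measure. Undefined
#' ratios (zero denominators) are reported as `NA` with a warning, never
#' silently as 0.
#'
#' @param predictions tibble/data frame with `patient_id` and `label`
#'   (`"positive"`/`"negative"`), or a named character vector.
#' @param gold gold-standard labels in the same form; the patient id sets
#'   must be identical.
#' @return A `psychscreen_eval` list: `tp`, `fp`, `fn`, `tn`, `n`,
#'   `accuracy`, `precision`, `recall`, `f_measure`.
#' @export
contingency <- function(predictions, gold) {
  pred <- as_label_vector(predictions, "predictions")
  gld <- as_label_vector(gold, "gold")
  only_pred <- setdiff(names(pred), names(gld))
  only_gold <- setdiff(names(gld), names(pred))
  if (length(only_pred) > 0 || length(only_gold) > 0) {
    stop("patient id sets differ; only in predictions: {",
         paste(only_pred, collapse = ", "), "}; only in gold: {",
         paste(only_gold, collapse = ", "), "}", call. = FALSE)
  }
  gld <- gld[names(pred)]
  tp <- sum(pred == "positive" & gld == "positive")
  fp <- sum(pred == "positive" & gld == "negative")
  fn <- sum(pred == "negative" & gld == "positive")
  tn <- sum(pred == "negative" & gld == "negative")
  n <- length(pred)
  precision <- if (tp + fp == 0) {
    warning("precision undefined: no positive predictions")
    NA_real_
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) {
    warning("recall undefined: no positive gold labels")
    NA_real_
  } else tp / (tp + fn)
  f <- if (is.na(precision) || is.na(recall)) {
    NA_real_
  } else if (precision + recall == 0) {
    warning("F-measure undefined: precision and recall are both zero")
    NA_real_
  } else {
    f_measure(precision, recall)
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
                 accuracy = (tp + tn) / n, precision = precision,
                 recall = recall, f_measure = f),
            class = "psychscreen_eval")
}

as_label_vector <- function(x, what) {
  if (is.data.frame(x)) {
    if (!"patient_id" %in% names(x) ||
          !any(c("label", "risk") %in% names(x))) {
      stop(what, " needs columns patient_id and label (or risk)",
           call. = FALSE)
    }
    lab <- if ("label" %in% names(x)) x$label else x$risk
    x <- stats::setNames(as.character(lab), x$patient_id)
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(what, " must carry patient ids (names or a patient_id column)",
         call. = FALSE)
  }
  bad <- setdiff(unique(x), c("positive", "negative"))
  if (length(bad) > 0) {
    stop(what, " labels must be 'positive'/'negative', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop(what, " has duplicate patient ids", call. = FALSE)
  }
  x
}

#' @export
print.psychscreen_eval <- function(x, ...) {
  cat("Screening evaluation (", x$n, " patients)\n", sep = "")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  accuracy  %s  precision %s\n  recall    %s  F-measure %s\n",
              fmt_pct(x$accuracy), fmt_pct(x$precision),
              fmt_pct(x$recall), fmt_pct(x$f_measure)))
  invisible(x)
}

fmt_pct <- function(v) {
  if (is.na(v)) "NA" else sprintf("%.2f (%d%%)", v, round(100 * v))
}

#' @export
as.data.frame.psychscreen_eval <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn, n = x$n,
             accuracy = x$accuracy, precision = x$precision,
             recall = x$recall, f_measure = x$f_measure)
}

#' Evaluate every positivity threshold (convenience extension)
#'
#' Sweeps the distinct-term threshold over `thresholds` and evaluates each
#' against the gold labels. A utility beyond the core single-threshold
#' algorithm, useful for picking an operating point on new cohorts.
#'
#' @param tallies per-patient tallies ([tally_patients()]).
#' @param gold gold labels (tibble with `patient_id`, `label`, or named
#'   vector).
#' @param thresholds integer vector of thresholds to evaluate.
#' @return Tibble with one row per threshold and the four metrics.
#' @export
sweep_thresholds <- function(tallies, gold, thresholds = 1:22) {
  rows <- lapply(thresholds, function(th) {
    calls <- classify_patients(tallies, classifier_config(th))
    rep <- suppressWarnings(
      contingency(stats::setNames(calls$risk, calls$patient_id), gold))
    cbind(tibble::tibble(threshold = th), as.data.frame(rep))
  })
  tibble::as_tibble(dplyr::bind_rows(rows))
}
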