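#' Compare multiple assessments of one laboratory
#'
#' Aligns two or more assessments (e.g. a baseline and a post-intervention
#' follow-up, or an external assessor against a self-assessment) on the
#' same instrument and scoring policy, and reports the per-scope score
#' series together with deltas relative to the first (baseline)
#' assessment. The spreadsheet workbook format holds at most 3
#' assessments; the library itself accepts any number >= 2.
#'
#' @param assessments List of `lmt_assessment` (ordered; the first is the
#'   baseline).
#' @param t An `lmt_taxonomy`.
#' @param policy Blank policy, see [scope_percent()].
#' @return An object of class `lmt_comparison`: list with `labels`,
#'   `policy`, `taxonomy`, `scopes` (data.frame: `scope_level`, `scope_id`,
#'   `scope_name`, one `percent.<label>` column per assessment, one
#'   `delta.<label>` column per non-baseline assessment), `completion`
#'   and `confidence` (named vectors), and `reports` (the underlying
#'   `lmt_score_report`s). A delta is `NA` wherever either side is
#'   Undefined.
#' @export
compare_assessments <- function(assessments, t,
                                policy = c("exclude", "blank_as_zero")) {
  policy <- match.arg(policy)
  if (length(assessments) < 2L)
    stop_lmt("comparison needs at least 2 assessments")
  stopifnot(all(vapply(assessments, inherits, TRUE, "lmt_assessment")))
  reports <- lapply(assessments, score_assessment, t = t, policy = policy)
  labels <- vapply(reports, `[[`, "", "label")
  if (anyDuplicated(labels))
    labels <- make.unique(labels, sep = " #")

  base <- report_scopes(reports[[1L]])
  scopes <- base[, c("scope_level", "scope_id", "scope_name")]
  series <- vapply(reports, function(r) report_scopes(r)$percent,
                   numeric(nrow(scopes)))
  colnames(series) <- labels
  for (j in seq_along(labels))
    scopes[[paste0("percent.", labels[j])]] <- series[, j]
  for (j in seq_along(labels)[-1L])
    scopes[[paste0("delta.", labels[j])]] <- series[, j] - series[, 1L]

  structure(
    list(labels = labels, policy = policy,
         taxonomy = reports[[1L]]$taxonomy,
         scopes = scopes,
         completion = setNames(
           vapply(reports, `[[`, 0, "completion_percent"), labels),
         confidence = setNames(
           vapply(reports, `[[`, "", "confidence_band"), labels),
         reports = reports),
    class = "lmt_comparison"
  )
}

#' Item-level concordance between two assessments
#'
#' Summarizes agreement between two assessors of the same laboratory over
#' the subcategories answered (with a level) by both: the count of exact
#' agreements, the histogram of absolute level differences, and the
#' proportion of exact agreement. Symmetric in its two arguments.
#'
#' @param a1,a2 `lmt_assessment` objects.
#' @param t An `lmt_taxonomy`.
#' @return List with `n_both_answered`, `n_agree`,
#'   `proportion_agreement` (`NA` when no overlap), and
#'   `abs_difference_histogram` (named integer vector over differences
#'   0..3).
#' @export
concordance <- function(a1, a2, t) {
  r1 <- aligned_responses(a1, t)
  r2 <- aligned_responses(a2, t)
  lv <- as.character(1:4)
  both <- r1 %in% lv & r2 %in% lv
  d <- abs(as.integer(r1[both]) - as.integer(r2[both]))
  hist <- table(factor(d, levels = 0:3))
  n <- sum(both)
  list(
    n_both_answered = n,
    n_agree = sum(d == 0L),
    proportion_agreement = if (n == 0L) NA_real_ else sum(d == 0L) / n,
    abs_difference_histogram = setNames(as.integer(hist), names(hist))
  )
}

#' @export
print.lmt_comparison <- function(x, ...) {
  cat("<lmt_comparison> ", length(x$labels), " assessments (policy: ",
      x$policy, ")\n", sep = "")
  ov <- x$scopes[x$scopes$scope_level == "overall", , drop = FALSE]
  for (lab in x$labels) {
    p <- ov[[paste0("percent.", lab)]]
    cat("  ", lab, ": overall ", fmt1(p), "  completion ",
        fmt1(x$completion[[lab]]), "% (", x$confidence[[lab]], ")\n",
        sep = "")
  }
  for (lab in x$labels[-1L]) {
    d <- ov[[paste0("delta.", lab)]]
    cat("  delta ", lab, " vs ", x$labels[1L], ": ",
        ifelse(is.na(d), "N/A", sprintf("%+.1f", d)), "\n", sep = "")
  }
  invisible(x)
}
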