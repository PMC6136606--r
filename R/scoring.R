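#' Percentage-of-optimum score for a set of responses
#'
#' The instrument scores every scope (a category, an area, or the whole
#' questionnaire) as a percentage of the optimum: a laboratory scoring the
#' top rubric level 4 on every assessed question reaches 100%. Questions
#' marked Not applicable are removed from numerator and denominator.
#'
#' Two blank policies are available, because the published score definition
#' does not state how unanswered questions enter the denominator:
#' \describe{
#'   \item{`"exclude"` (default)}{blanks are excluded from scoring
#'     altogether; incompleteness is reflected only in the confidence
#'     score. `percent = 100 * sum(levels) / (4 * n_answered)`. Defined
#'     percents therefore lie in \[25, 100\].}
#'   \item{`"blank_as_zero"`}{a blank contributes 0 to the numerator but
#'     counts in the denominator, so unanswered questions penalize the
#'     score; percents lie in \[0, 100\].}
#' }
#'
#' @param responses Character vector of canonical responses
#'   (`"1"`..`"4"`, `"NA"`, `""`).
#' @param policy `"exclude"` or `"blank_as_zero"`.
#' @return The percent (full precision), or `NA_real_` (Undefined) when
#'   the scope has no applicable responses under the policy.
#' @export
scope_percent <- function(responses, policy = c("exclude", "blank_as_zero")) {
  policy <- match.arg(policy)
  r <- canonical_response(responses)
  levels <- suppressWarnings(as.integer(r[r %in% as.character(1:4)]))
  n_blank <- sum(r == "")
  num <- sum(levels)
  denom_n <- if (policy == "exclude") length(levels) else
    length(levels) + n_blank
  if (denom_n == 0L) return(NA_real_)
  100 * num / (4 * denom_n)
}

#' Completion percentage of an assessment
#'
#' The fraction of the questionnaire that was completed, i.e. not left
#' blank. A Not-applicable response is a completed response: the assessor
#' considered the question and ruled it out.
#'
#' @param a An `lmt_assessment`.
#' @param t The bound `lmt_taxonomy`.
#' @return Percent in \[0, 100\] (full precision).
#' @export
completion_percent <- function(a, t) {
  r <- aligned_responses(a, t)
  100 * sum(r != "") / length(r)
}

#' Confidence band of a completion percentage
#'
#' Completion of 0--69% of the questionnaire gives a low confidence score,
#' 70--89% medium, and 90--100% is ranked reliable. Boundaries are
#' lower-inclusive half-open intervals (\[0,70) low, \[70,90) medium,
#' \[90,100\] reliable), which reproduces the printed integer ranges.
#'
#' @param completion Completion percent in \[0, 100\] (vectorized).
#' @return Character vector: `"low"`, `"medium"` or `"reliable"`.
#' @export
confidence_band <- function(completion) {
  if (any(is.na(completion)) || any(completion < 0 | completion > 100))
    stop_lmt("completion must be within [0, 100]")
  ifelse(completion < 70, "low",
         ifelse(completion < 90, "medium", "reliable"))
}

#' Radar band of a percentage score
#'
#' Scores are ranked into five 20-point bands (0--20%, 20--40%, 40--60%,
#' 60--80%, 80--100%) used to color the radar-style chart. Bands are
#' lower-inclusive; the top band is closed so 100 maps to band 4.
#'
#' @param percent Percent in \[0, 100\], or `NA` for an undefined scope
#'   (vectorized).
#' @return Integer band index 0..4 (`NA` for undefined scopes).
#' @export
radar_band <- function(percent) {
  ok <- is.na(percent) | (percent >= 0 & percent <= 100)
  if (!all(ok)) stop_lmt("percent must be within [0, 100]")
  band <- floor(percent / 20)
  band[!is.na(percent) & percent == 100] <- 4L
  as.integer(band)
}

#' Score one assessment at every scope
#'
#' Converts an assessment's responses into percentage-of-optimum scores
#' overall, per area and per category, plus the completion percentage and
#' its confidence band. All scores aggregate over subcategories with equal
#' weight (the overall score is *not* the mean of category scores unless
#' applicable counts are equal). Scopes with no applicable response are
#' Undefined (`NA`) and render as "N/A".
#'
#' Full precision is retained in the returned object; rounding to one
#' decimal happens only at presentation ([format()]/[print()] and the
#' rendered tables).
#'
#' @param a An `lmt_assessment`.
#' @param t An `lmt_taxonomy`.
#' @param policy Blank policy, see [scope_percent()].
#' @return An object of class `lmt_score_report`: list with `label`,
#'   `policy`, `taxonomy` (name/version stamp), `overall`, `per_area` and
#'   `per_category` (data.frames with columns `scope_id`, `scope_name`,
#'   `percent`, `answered`, `applicable`, `total`, `radar_band`),
#'   `completion_percent` and `confidence_band`.
#' @export
score_assessment <- function(a, t, policy = c("exclude", "blank_as_zero")) {
  policy <- match.arg(policy)
  r <- aligned_responses(a, t)
  idx <- taxonomy_index(t)

  scope_row <- function(scope_id, scope_name, ids) {
    rr <- r[ids]
    answered <- sum(rr != "")                 # includes N/A: the assessor responded
    applicable <- sum(rr %in% as.character(1:4))  # answered, non-N/A
    pct <- scope_percent(rr, policy)
    data.frame(
      scope_id = scope_id, scope_name = scope_name,
      percent = pct, answered = answered, applicable = applicable,
      total = length(ids), radar_band = radar_band(pct),
      stringsAsFactors = FALSE
    )
  }

  per_category <- do.call(rbind, lapply(unique(idx$category_id), function(cid) {
    sub <- idx[idx$category_id == cid, ]
    scope_row(cid, sub$category_name[1], sub$subcategory_id)
  }))
  per_area <- do.call(rbind, lapply(unique(idx$area_id), function(aid) {
    sub <- idx[idx$area_id == aid, ]
    scope_row(aid, sub$area_name[1], sub$subcategory_id)
  }))
  overall <- scope_row("overall", "Overall", idx$subcategory_id)

  completion <- 100 * sum(r != "") / length(r)
  structure(
    list(label = a$label, policy = policy,
         taxonomy = list(name = t$name, version = t$version),
         overall = overall, per_area = per_area,
         per_category = per_category,
         completion_percent = completion,
         confidence_band = confidence_band(completion)),
    class = "lmt_score_report"
  )
}

# All scopes of a report as one data.frame (overall, areas, categories,
# instrument order), used by comparison/aggregation/reporting.
report_scopes <- function(rep) {
  rbind(
    cbind(scope_level = "overall", rep$overall),
    cbind(scope_level = "area", rep$per_area),
    cbind(scope_level = "category", rep$per_category)
  )
}

#' @export
format.lmt_score_report <- function(x, ...) {
  sc <- report_scopes(x)
  lines <- c(
    sprintf("Score report '%s' (policy: %s)", x$label, x$policy),
    sprintf("  %-45s %6s  band", "scope", "%"),
    sprintf("  %-45s %6s  %s",
            paste0(ifelse(sc$scope_level == "category", "  ", ""),
                   sc$scope_name),
            fmt1(sc$percent),
            ifelse(is.na(sc$radar_band), "N/A", sc$radar_band)),
    sprintf("  completion: %s%%  confidence: %s",
            fmt1(x$completion_percent), x$confidence_band)
  )
  paste(lines, collapse = "\n")
}

#' @export
print.lmt_score_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
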