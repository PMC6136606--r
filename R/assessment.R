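#' One laboratory's assessment responses
#'
#' An `lmt_assessment` holds the responses of a single assessment of one
#' laboratory: for each subcategory of the bound instrument, one of
#' \itemize{
#'   \item an answered rubric level (`"1"`..`"4"`),
#'   \item `"NA"` — Not applicable, which removes the question from both
#'     numerator and denominator of every score, or
#'   \item blank (`""`, or simply no entry) — left unanswered; blanks feed
#'     the completion-based confidence score.
#' }
#' plus free-form laboratory metadata and assessment metadata (label, date,
#' assessor role).
#'
#' @param responses Named character vector (or coercible list) mapping
#'   subcategory ids to `"1"`..`"4"`, `"NA"` (case-insensitive) or `""`.
#'   Integer levels are accepted and converted. Missing subcategories are
#'   treated as blank.
#' @param label Assessment label (used in reports and legends).
#' @param lab_info Named list of laboratory metadata (name, country, tier,
#'   contact, ... — all optional).
#' @param date Assessment date string (optional).
#' @param assessor One of `"external"` or `"self"` (optional).
#' @return An object of class `lmt_assessment`.
#' @export
new_assessment <- function(responses = character(), label = "assessment",
                           lab_info = list(), date = NULL,
                           assessor = NULL) {
  if (is.list(responses)) responses <- unlist(responses)
  ids <- names(responses)
  if (length(responses) > 0L && (is.null(ids) || any(!nzchar(ids))))
    stop_lmt("responses must be named by subcategory id")
  if (anyDuplicated(ids))
    stop_lmt("duplicate response for subcategory id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- canonical_response(as.character(responses))
  names(vals) <- ids
  if (!is.null(assessor) && !assessor %in% c("external", "self"))
    stop_lmt("assessor must be 'external' or 'self'")
  structure(
    list(label = label, lab_info = lab_info,
         meta = list(date = date, assessor = assessor),
         responses = vals),
    class = "lmt_assessment"
  )
}

# Normalize raw response tokens to the canonical {"", "NA", "1".."4"}.
canonical_response <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  up <- toupper(x)
  x[up == "NA"] <- "NA"
  bad <- !(x %in% c("", "NA", "1", "2", "3", "4"))
  if (any(bad))
    stop_lmt("illegal response value(s): ",
             paste(unique(x[bad]), collapse = ", "),
             " (expected 1..4, NA, or blank)")
  x
}

#' Check an assessment against a taxonomy
#'
#' Verifies that every response references a subcategory of the taxonomy.
#'
#' @param a An `lmt_assessment`.
#' @param t An `lmt_taxonomy`.
#' @return `a`, invisibly; errors (naming the offending ids) otherwise.
#' @export
validate_assessment <- function(a, t) {
  stopifnot(inherits(a, "lmt_assessment"), inherits(t, "lmt_taxonomy"))
  known <- taxonomy_index(t)$subcategory_id
  unknown <- setdiff(names(a$responses), known)
  if (length(unknown) > 0L)
    stop_lmt("response(s) reference unknown subcategory id(s): ",
             paste(unknown, collapse = ", "),
             class = "lmt_validation_error")
  invisible(a)
}

# Responses aligned to taxonomy order, one entry per subcategory
# (missing entry == blank). Used by every scoring path.
aligned_responses <- function(a, t) {
  validate_assessment(a, t)
  ids <- taxonomy_index(t)$subcategory_id
  out <- setNames(rep("", length(ids)), ids)
  out[names(a$responses)] <- a$responses
  out
}

#' @export
print.lmt_assessment <- function(x, ...) {
  v <- x$responses
  cat("<lmt_assessment> '", x$label, "'\n", sep = "")
  if (length(x$lab_info) > 0L && !is.null(x$lab_info$name))
    cat("  laboratory: ", x$lab_info$name, "\n", sep = "")
  cat("  responses: ", sum(v %in% as.character(1:4)), " answered, ",
      sum(v == "NA"), " N/A, ", sum(v == ""), " blank (recorded)\n", sep = "")
  invisible(x)
}
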