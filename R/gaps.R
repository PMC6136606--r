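#' Gap analysis: from scores to an improvement plan
#'
#' The four rubric levels of every question form a progression: each
#' increasing level describes the additional practice or management
#' required to advance. The gap report turns a scored assessment into an
#' improvement plan by surfacing, for every answered question below the
#' optimum level 4, the next level's practice text. Questions left blank
#' are not dropped: they appear in a separate "unassessed" section whose
#' recommended action is to establish a baseline starting from the level-1
#' practice.
#'
#' Items are ordered weakest-category-first: ascending category percent
#' under the chosen policy (Undefined categories last), then instrument
#' order within a category. The output is a pure function of
#' (assessment, taxonomy, policy).
#'
#' @param a An `lmt_assessment`.
#' @param t An `lmt_taxonomy`.
#' @param policy Blank policy, see [scope_percent()].
#' @return An object of class `lmt_gap_report`: a data.frame with columns
#'   `section` (`"gap"` or `"unassessed"`), `subcategory_id`,
#'   `subcategory_name`, `category_id`, `category_name`,
#'   `current_level` (`NA` for unassessed), `next_level`, `action`
#'   (`"advance"` / `"establish baseline"`), `next_practice_text`,
#'   `category_percent`. No row is emitted for level-4 or Not-applicable
#'   responses.
#' @export
gap_report <- function(a, t, policy = c("exclude", "blank_as_zero")) {
  policy <- match.arg(policy)
  r <- aligned_responses(a, t)
  idx <- taxonomy_index(t)
  rep <- score_assessment(a, t, policy)
  cat_pct <- setNames(rep$per_category$percent, rep$per_category$scope_id)

  rows <- list()
  for (i in seq_len(nrow(idx))) {
    id <- idx$subcategory_id[i]
    v <- r[[id]]
    if (v == "NA" || v == "4") next
    sc <- taxonomy_subcategory(t, id)
    if (v == "") {
      cur <- NA_integer_; nxt <- 1L; action <- "establish baseline"
      section <- "unassessed"
    } else {
      cur <- as.integer(v); nxt <- cur + 1L; action <- "advance"
      section <- "gap"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      section = section,
      subcategory_id = id,
      subcategory_name = idx$subcategory_name[i],
      category_id = idx$category_id[i],
      category_name = idx$category_name[i],
      current_level = cur,
      next_level = nxt,
      action = action,
      next_practice_text = sc$rubric[[as.character(nxt)]],
      category_percent = unname(cat_pct[idx$category_id[i]]),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    out <- data.frame(
      section = character(), subcategory_id = character(),
      subcategory_name = character(), category_id = character(),
      category_name = character(), current_level = integer(),
      next_level = integer(), action = character(),
      next_practice_text = character(), category_percent = numeric(),
      stringsAsFactors = FALSE
    )
  } else {
    out <- do.call(rbind, rows)
    # gaps before unassessed; within a section, weakest category first,
    # Undefined category percents last, instrument order as tie-break
    pct_key <- ifelse(is.na(out$category_percent), Inf, out$category_percent)
    out <- out[order(match(out$section, c("gap", "unassessed")),
                     pct_key, seq_len(nrow(out))), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("lmt_gap_report", "data.frame"),
            label = a$label, policy = policy)
}

#' @export
print.lmt_gap_report <- function(x, ...) {
  cat("Gap report '", attr(x, "label"), "' (policy: ", attr(x, "policy"),
      ")\n", sep = "")
  if (nrow(x) == 0L) {
    cat("  no gaps: every answered subcategory is at the optimum level\n")
    return(invisible(x))
  }
  for (section in intersect(c("gap", "unassessed"), x$section)) {
    xx <- x[x$section == section, , drop = FALSE]
    cat(if (section == "gap") "Improvement opportunities:\n"
        else "Unassessed (establish baseline):\n")
    last_cat <- ""
    for (i in seq_len(nrow(xx))) {
      if (xx$category_name[i] != last_cat) {
        last_cat <- xx$category_name[i]
        cat(sprintf("  %s (%s%%)\n", last_cat, fmt1(xx$category_percent[i])))
      }
      cat(sprintf("    %s [%s -> %d]: %s\n", xx$subcategory_name[i],
                  ifelse(is.na(xx$current_level[i]), "blank",
                         xx$current_level[i]),
                  xx$next_level[i],
                  substr(xx$next_practice_text[i], 1, 70)))
    }
  }
  invisible(x)
}
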