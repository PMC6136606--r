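## Interchange formats for assessments.
##
## Three formats carry the same payload: a versioned JSON envelope (the
## canonical machine format), a flat CSV (one row per subcategory), and a
## 6-sheet plain-text workbook mirroring the instrument's spreadsheet
## layout. Scoring an assessment read from any of them yields identical
## results. The Not-applicable marker is the literal string "NA"
## (case-insensitive); an empty cell means Blank. All files are UTF-8.

ASSESSMENT_SCHEMA_VERSION <- "1.0"
WORKBOOK_VERSION <- "1.0"

# Fixed 6-sheet layout of the workbook.
WORKBOOK_SHEETS <- c("Safety Index", "User Guideline",
                     "Laboratory Information", "Safety Module",
                     "Safety Summary", "Rights and Attribution")

#' Write an assessment to the canonical JSON envelope
#'
#' @param a An `lmt_assessment`.
#' @param path Output path.
#' @param t Optional `lmt_taxonomy`; when given, responses are validated
#'   and a taxonomy reference (name/version) is stamped into the envelope.
#' @return `path`, invisibly.
#' @export
write_assessment_json <- function(a, path, t = NULL) {
  stopifnot(inherits(a, "lmt_assessment"))
  if (!is.null(t)) validate_assessment(a, t)
  resp <- a$responses[a$responses != ""]
  meta <- list(label = a$label, date = a$meta$date,
               assessor = a$meta$assessor)
  doc <- list(
    format = "lmt-assessment",
    schema_version = ASSESSMENT_SCHEMA_VERSION,
    taxonomy_ref = if (is.null(t)) NULL else
      list(name = t$name, version = t$version),
    lab_info = a$lab_info,
    meta = meta[!vapply(meta, is.null, TRUE)],
    responses = as.list(resp)
  )
  jsonlite::write_json(doc[!vapply(doc, is.null, TRUE)], path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read an assessment from the canonical JSON envelope
#'
#' @param path Input path.
#' @param t Optional `lmt_taxonomy` to validate against.
#' @return An `lmt_assessment`.
#' @export
read_assessment_json <- function(path, t = NULL) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_lmt("cannot parse '", path, "': ",
                             conditionMessage(e), class = "lmt_parse_error"))
  if (!identical(doc$format, "lmt-assessment"))
    stop_lmt("'", path, "' is not an assessment envelope",
             class = "lmt_parse_error")
  if (!identical(doc$schema_version, ASSESSMENT_SCHEMA_VERSION))
    stop_lmt("schema-version mismatch in '", path, "': got '",
             doc$schema_version %||% "<missing>", "', expected '",
             ASSESSMENT_SCHEMA_VERSION, "'", class = "lmt_parse_error")
  scalar <- function(x) if (is.character(x) && length(x) == 1L &&
                            !is.na(x)) x else NULL
  a <- new_assessment(
    responses = unlist(doc$responses) %||% character(),
    label = scalar(doc$meta$label) %||% "assessment",
    lab_info = doc$lab_info %||% list(),
    date = scalar(doc$meta$date), assessor = scalar(doc$meta$assessor)
  )
  if (!is.null(t)) validate_assessment(a, t)
  a
}

#' Write an assessment as flat CSV
#'
#' One row per subcategory in instrument order (`subcategory_id,response`);
#' blank responses are written as an empty field, Not applicable as `NA`.
#' The CSV carries only the response payload, not laboratory metadata.
#'
#' @param a An `lmt_assessment`.
#' @param path Output path.
#' @param t An `lmt_taxonomy` (fixes row set and order).
#' @return `path`, invisibly.
#' @export
write_assessment_csv <- function(a, path, t) {
  r <- aligned_responses(a, t)
  df <- data.frame(subcategory_id = names(r), response = unname(r),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an assessment from flat CSV
#'
#' @param path Input path (columns `subcategory_id`, `response`).
#' @param t Optional `lmt_taxonomy` to validate against.
#' @param label Label for the resulting assessment.
#' @return An `lmt_assessment`.
#' @export
read_assessment_csv <- function(path, t = NULL, label = "assessment") {
  # na.strings empty: the literal "NA" is the Not-applicable marker,
  # not a missing value
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character",
                        na.strings = character(), fileEncoding = "UTF-8")
  if (!all(c("subcategory_id", "response") %in% names(df)))
    stop_lmt("CSV '", path,
             "' must have columns subcategory_id, response",
             class = "lmt_parse_error")
  dup <- unique(df$subcategory_id[duplicated(df$subcategory_id)])
  if (length(dup) > 0L)
    stop_lmt("duplicate subcategory row(s) in '", path, "': ",
             paste(dup, collapse = ", "), class = "lmt_parse_error")
  vals <- tryCatch(canonical_response(df$response), error = function(e)
    stop_lmt("in '", path, "': ", conditionMessage(e),
             class = "lmt_parse_error"))
  names(vals) <- df$subcategory_id
  a <- new_assessment(vals[vals != ""], label = label)
  if (!is.null(t)) validate_assessment(a, t)
  a
}

## ---- plain-text workbook -------------------------------------------------

sheet_header <- function(k) {
  sprintf("== SHEET %d: %s ==", k, WORKBOOK_SHEETS[k])
}

#' Write assessments to the 6-sheet plain-text workbook
#'
#' The workbook mirrors the instrument's spreadsheet layout as a single
#' UTF-8 text file with six named sheets in fixed order: (1) an index
#' describing the tool, (2) a user guideline, (3) laboratory information,
#' (4) the safety module questionnaire — one row per subcategory in
#' instrument order with up to 3 assessment columns, (5) the safety
#' summary — tabulated scores and confidence lines regenerated from the
#' assessments, and (6) rights/attribution. Output is byte-stable for
#' identical inputs (no timestamp is written unless one is supplied).
#'
#' @param assessments List of 1..3 `lmt_assessment` (more errors unless
#'   `truncate = TRUE`, which warns and keeps the first 3 — the workbook
#'   format's limit, not the library's).
#' @param path Output path.
#' @param t An `lmt_taxonomy`.
#' @param lab_info Named list of laboratory metadata; defaults to the
#'   first assessment's.
#' @param policy Blank policy used for the summary sheet.
#' @param truncate Keep the first 3 assessments when more are given.
#' @param timestamp Optional fixed timestamp string recorded on sheet 1.
#' @return `path`, invisibly.
#' @export
write_assessments_workbook <- function(assessments, path, t,
                                       lab_info = NULL,
                                       policy = c("exclude", "blank_as_zero"),
                                       truncate = FALSE, timestamp = NULL) {
  policy <- match.arg(policy)
  if (inherits(assessments, "lmt_assessment")) assessments <- list(assessments)
  if (length(assessments) == 0L) stop_lmt("no assessments to write")
  if (length(assessments) > 3L) {
    if (!isTRUE(truncate))
      stop_lmt("workbook format holds at most 3 assessments (got ",
               length(assessments), "); pass truncate = TRUE to keep ",
               "the first 3")
    warning("workbook format holds at most 3 assessments; writing the ",
            "first 3 of ", length(assessments), call. = FALSE)
    assessments <- assessments[1:3]
  }
  lab_info <- lab_info %||% assessments[[1L]]$lab_info
  reports <- lapply(assessments, score_assessment, t = t, policy = policy)
  labels <- vapply(assessments, `[[`, "", "label")
  idx <- taxonomy_index(t)

  lines <- c(
    paste("lmt-workbook", WORKBOOK_VERSION),
    sheet_header(1L),
    "Laboratory safety and biosecurity assessment workbook.",
    paste0("Instrument: ", t$name, " (version ", t$version, ")"),
    if (!is.null(timestamp)) paste0("generated\t", timestamp),
    sheet_header(2L),
    "Score each subcategory 1 (most basic) to 4 (optimal practice);",
    "enter NA if a subcategory does not apply to this laboratory;",
    "leave blank if not assessed. Blanks lower the confidence score only.",
    sheet_header(3L)
  )
  for (k in names(lab_info))
    lines <- c(lines, paste0("lab.", k, "\t", lab_info[[k]]))
  for (j in seq_along(assessments)) {
    m <- assessments[[j]]$meta
    lines <- c(lines,
               paste0("assessment", j, ".label\t", labels[j]),
               if (!is.null(m$date))
                 paste0("assessment", j, ".date\t", m$date),
               if (!is.null(m$assessor))
                 paste0("assessment", j, ".assessor\t", m$assessor))
  }

  lines <- c(lines, sheet_header(4L),
             paste(c("subcategory_id", "subcategory_name", labels),
                   collapse = "\t"))
  aligned <- lapply(assessments, aligned_responses, t = t)
  for (i in seq_len(nrow(idx))) {
    cells <- vapply(aligned, function(r) r[[idx$subcategory_id[i]]], "")
    lines <- c(lines, paste(c(idx$subcategory_id[i],
                              idx$subcategory_name[i], cells),
                            collapse = "\t"))
  }

  lines <- c(lines, sheet_header(5L),
             paste0("policy\t", policy),
             format(render_summary_tables(reports)),
             sheet_header(6L),
             "Assessment instrument layout reconstructed for interchange;",
             "assessment data remains the property of the assessed",
             "laboratory and its administration.")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read assessments from the 6-sheet plain-text workbook
#'
#' @param path Input path.
#' @param t An `lmt_taxonomy` (validates row set and values; a cell
#'   outside `{1,2,3,4, NA, empty}` or an unknown subcategory row is an
#'   error naming the sheet, row and column).
#' @return List with `lab_info` (named list) and `assessments` (list of
#'   `lmt_assessment`, one per assessment column).
#' @export
read_assessments_workbook <- function(path, t) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1L], "lmt-workbook"))
    stop_lmt("'", path, "' is not an lmt workbook",
             class = "lmt_parse_error")
  starts <- grep("^== SHEET [0-9]+: .* ==$", lines)
  got <- sub("^== SHEET [0-9]+: (.*) ==$", "\\1", lines[starts])
  if (length(got) != 6L || !identical(got, WORKBOOK_SHEETS))
    stop_lmt("workbook must contain the 6 sheets ",
             paste(WORKBOOK_SHEETS, collapse = " | "),
             " in order; found: ", paste(got, collapse = " | "),
             class = "lmt_parse_error")
  sheet <- function(k) {
    from <- starts[k] + 1L
    to <- if (k < 6L) starts[k + 1L] - 1L else length(lines)
    if (from > to) character() else lines[from:to]
  }

  # sheet 3: laboratory information and per-assessment metadata
  lab_info <- list(); meta <- list()
  for (ln in sheet(3L)) {
    kv <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) next
    key <- kv[1L]; val <- paste(kv[-1L], collapse = "\t")
    if (startsWith(key, "lab.")) {
      lab_info[[substring(key, 5L)]] <- val
    } else if (grepl("^assessment[0-9]+\\.", key)) {
      j <- sub("^assessment([0-9]+)\\..*$", "\\1", key)
      f <- sub("^assessment[0-9]+\\.", "", key)
      meta[[j]] <- c(meta[[j]], setNames(val, f))
    }
  }

  # sheet 4: the questionnaire grid
  grid <- sheet(4L)
  if (length(grid) < 2L)
    stop_lmt("Safety Module sheet is empty", class = "lmt_parse_error")
  header <- strsplit(grid[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L ||
      !identical(header[1:2], c("subcategory_id", "subcategory_name")))
    stop_lmt("Safety Module sheet must start with columns ",
             "subcategory_id, subcategory_name and at least one ",
             "assessment column", class = "lmt_parse_error")
  labels <- header[-(1:2)]
  if (length(labels) > 3L)
    stop_lmt("Safety Module sheet has ", length(labels),
             " assessment columns; the workbook layout allows at most 3",
             class = "lmt_parse_error")
  known <- taxonomy_index(t)$subcategory_id
  resp <- lapply(labels, function(...) character())
  for (i in seq_along(grid)[-1L]) {
    cells <- strsplit(grid[i], "\t", fixed = TRUE)[[1L]]
    length(cells) <- length(header)
    cells[is.na(cells)] <- ""
    id <- cells[1L]
    if (!id %in% known)
      stop_lmt("Safety Module sheet row ", i, ": unknown subcategory '",
               id, "'", class = "lmt_parse_error")
    for (j in seq_along(labels)) {
      v <- tryCatch(canonical_response(cells[2L + j]), error = function(e)
        stop_lmt("Safety Module sheet row ", i, ", column '", labels[j],
                 "': ", conditionMessage(e), class = "lmt_parse_error"))
      if (v != "") resp[[j]][[id]] <- v
    }
  }
  getf <- function(m, f) if (!is.null(m) && f %in% names(m))
    unname(m[[f]]) else NULL
  assessments <- lapply(seq_along(labels), function(j) {
    m <- meta[[as.character(j)]]
    a <- new_assessment(resp[[j]], label = labels[j], lab_info = lab_info,
                        date = getf(m, "date"),
                        assessor = getf(m, "assessor"))
    validate_assessment(a, t)
  })
  list(lab_info = lab_info, assessments = assessments)
}
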