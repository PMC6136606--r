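#' The assessment instrument: areas, categories, subcategories, rubrics
#'
#' An `lmt_taxonomy` is the definition of a laboratory safety and
#' biosecurity assessment instrument: an ordered tree of *areas* (top tier,
#' e.g. Administration, Operations, Engineering, PPE), *categories*
#' (groups of related practices, e.g. Waste disposal), and *subcategories*
#' (single scored questions). Every subcategory carries a four-level
#' scoring rubric in which level 4 describes the optimal practice and
#' level 1 the most basic, plus optional assessor guidance text.
#'
#' The instrument is data, not code: taxonomies are loaded from a
#' versioned JSON schema document (see [load_taxonomy()]) so that
#' alternative instruments can be assessed with the same engine. The
#' standard 98-question safety module ships with the package
#' ([builtin_lmt_s()]).
#'
#' @param name Instrument name.
#' @param version Instrument version string.
#' @param areas List of areas, each a list with `id`, `name` and
#'   `categories`; each category has `id`, `name`, `area_id` and
#'   `subcategories`; each subcategory has `id`, `name`, `category_id`,
#'   `guidance`, optional `placeholder` flag, and `rubric`, a list mapping
#'   levels `"1"`..`"4"` to practice text.
#' @return An object of class `lmt_taxonomy`.
#' @seealso [validate_taxonomy()], [taxonomy_index()]
#' @export
new_taxonomy <- function(name, version, areas) {
  t <- structure(
    list(name = name, version = version, areas = areas),
    class = "lmt_taxonomy"
  )
  findings <- validate_taxonomy(t)
  if (nrow(findings) > 0L) {
    stop_lmt(
      "invalid taxonomy (", nrow(findings), " finding(s)):\n",
      paste0("  [", findings$rule, "] ", findings$path, ": ",
             findings$message, collapse = "\n"),
      class = "lmt_validation_error"
    )
  }
  t
}

#' Flat index of a taxonomy
#'
#' One row per subcategory, in instrument order (the order used on every
#' report table and radar axis).
#'
#' @param t An `lmt_taxonomy`.
#' @return A data.frame with columns `subcategory_id`, `subcategory_name`,
#'   `category_id`, `category_name`, `area_id`, `area_name`.
#' @export
taxonomy_index <- function(t) {
  stopifnot(inherits(t, "lmt_taxonomy"))
  rows <- list()
  for (ar in t$areas) {
    for (ca in ar$categories) {
      for (sc in ca$subcategories) {
        rows[[length(rows) + 1L]] <- data.frame(
          subcategory_id = sc$id,
          subcategory_name = sc$name,
          category_id = ca$id,
          category_name = ca$name,
          area_id = ar$id,
          area_name = ar$name,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Look up one subcategory by id
#'
#' @param t An `lmt_taxonomy`.
#' @param id Subcategory id.
#' @return The subcategory node (list), or an error if the id is unknown.
#' @export
taxonomy_subcategory <- function(t, id) {
  for (ar in t$areas) for (ca in ar$categories) for (sc in ca$subcategories)
    if (identical(sc$id, id)) return(sc)
  stop_lmt("unknown subcategory id: ", id)
}

#' Validate a taxonomy against the instrument invariants
#'
#' Checks every typed invariant of the instrument model: unique ids,
#' non-empty names, each subcategory carrying rubric levels 1--4 exactly
#' once with non-empty practice text, parent references that resolve, and
#' at least one child per area and category. Violations are reported as
#' findings, not thrown.
#'
#' @param t An `lmt_taxonomy` (or a bare list with the same shape).
#' @return A data.frame of findings with columns `rule`, `path`,
#'   `message`; zero rows iff the taxonomy is valid.
#' @export
validate_taxonomy <- function(t) {
  findings <- list()
  add <- function(rule, path, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      rule = rule, path = path, message = message, stringsAsFactors = FALSE
    )
  }
  empty <- function(x) is.null(x) || !is.character(x) || length(x) != 1L ||
    is.na(x) || !nzchar(x)

  if (empty(t$name)) add("empty-name", "taxonomy", "instrument name is empty")
  if (empty(t$version)) add("empty-version", "taxonomy", "version is empty")
  if (length(t$areas) == 0L) {
    add("empty-taxonomy", "taxonomy", "no areas defined")
  }

  seen <- character(0)
  check_id <- function(id, path) {
    if (empty(id)) {
      add("empty-id", path, "missing id")
      return(invisible())
    }
    if (id %in% seen) add("duplicate-id", path, paste0("id '", id, "' already used"))
    seen <<- c(seen, id)
  }

  for (ai in seq_along(t$areas)) {
    ar <- t$areas[[ai]]
    apath <- paste0("areas[", ai, "]")
    check_id(ar$id, apath)
    if (empty(ar$name)) add("empty-name", apath, "area name is empty")
    if (length(ar$categories) == 0L)
      add("empty-area", apath, "area has no categories")
    for (ci in seq_along(ar$categories)) {
      ca <- ar$categories[[ci]]
      cpath <- paste0(apath, ".categories[", ci, "]")
      check_id(ca$id, cpath)
      if (empty(ca$name)) add("empty-name", cpath, "category name is empty")
      if (!is.null(ca$area_id) && !identical(ca$area_id, ar$id))
        add("dangling-reference", cpath,
            paste0("area_id '", ca$area_id, "' does not resolve to parent area '",
                   ar$id, "'"))
      if (length(ca$subcategories) == 0L)
        add("empty-category", cpath, "category has no subcategories")
      for (si in seq_along(ca$subcategories)) {
        sc <- ca$subcategories[[si]]
        spath <- paste0(cpath, ".subcategories[", si, "]")
        check_id(sc$id, spath)
        if (empty(sc$name)) add("empty-name", spath, "subcategory name is empty")
        if (!is.null(sc$category_id) && !identical(sc$category_id, ca$id))
          add("dangling-reference", spath,
              paste0("category_id '", sc$category_id,
                     "' does not resolve to parent category '", ca$id, "'"))
        lv <- names(sc$rubric)
        for (k in c("1", "2", "3", "4")) {
          if (sum(lv == k) != 1L) {
            add("missing-rubric-level", spath,
                paste0("rubric must define level ", k, " exactly once"))
          } else if (empty(sc$rubric[[k]])) {
            add("empty-practice-text", spath,
                paste0("rubric level ", k, " has empty practice text"))
          }
        }
        if (any(!lv %in% c("1", "2", "3", "4")))
          add("unknown-rubric-level", spath,
              paste0("rubric defines levels outside 1..4: ",
                     paste(setdiff(lv, c("1", "2", "3", "4")), collapse = ", ")))
      }
    }
  }
  if (length(findings) == 0L) {
    return(data.frame(rule = character(), path = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Load a taxonomy from its JSON schema document
#'
#' The schema dialect is a versioned JSON envelope:
#' \preformatted{
#' {"format": "lmt-taxonomy", "schema_version": "1.0",
#'  "name": ..., "version": ...,
#'  "areas": [{"id", "name", "categories": [
#'     {"id", "name", "area_id", "subcategories": [
#'        {"id", "name", "category_id", "guidance", "placeholder",
#'         "rubric": {"1": text, ..., "4": text}}]}]}]}
#' }
#'
#' @param path Path to a schema document.
#' @return A validated `lmt_taxonomy`.
#' @export
load_taxonomy <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop_lmt("cannot parse schema document '", path,
                                 "': ", conditionMessage(e),
                                 class = "lmt_parse_error")
  )
  if (!identical(doc$format, "lmt-taxonomy"))
    stop_lmt("not a taxonomy schema document (format field is '",
             doc$format %||% "<missing>", "')", class = "lmt_parse_error")
  new_taxonomy(name = doc$name, version = doc$version, areas = doc$areas)
}

#' Serialize a taxonomy to its JSON schema document
#'
#' Writing then reloading reproduces an identical taxonomy (round-trip
#' identity).
#'
#' @param t An `lmt_taxonomy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(t, path) {
  stopifnot(inherits(t, "lmt_taxonomy"))
  doc <- list(format = "lmt-taxonomy", schema_version = "1.0",
              name = t$name, version = t$version, areas = t$areas)
  # compact on purpose: the packaged 98-question instrument must stay small
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

.lmt_env <- new.env(parent = emptyenv())

#' The built-in 98-question safety and biosecurity instrument
#'
#' Returns the packaged standard instrument: 4 areas, 20 categories and 98
#' subcategories (Administration 15, Operations 38, Engineering 32, PPE 13).
#' The "Disposable glove usage" subcategory carries its full published
#' four-level rubric; all other subcategories carry clearly labelled
#' placeholder rubric text and placeholder names, because the instrument's
#' full question text is not published.
#'
#' @return An `lmt_taxonomy`.
#' @export
builtin_lmt_s <- function() {
  if (is.null(.lmt_env$builtin)) {
    path <- system.file("extdata", "lmt_s.json", package = "lmtscore",
                        mustWork = TRUE)
    .lmt_env$builtin <- load_taxonomy(path)
  }
  .lmt_env$builtin
}

#' @export
print.lmt_taxonomy <- function(x, ...) {
  idx <- taxonomy_index(x)
  cat("<lmt_taxonomy> ", x$name, " (version ", x$version, ")\n", sep = "")
  cat("  ", length(x$areas), " areas, ",
      length(unique(idx$category_id)), " categories, ",
      nrow(idx), " subcategories\n", sep = "")
  for (ar in x$areas) {
    n <- sum(idx$area_id == ar$id)
    cat("  - ", ar$name, ": ", length(ar$categories), " categories, ",
        n, " subcategories\n", sep = "")
  }
  invisible(x)
}
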