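# Fixtures are built in code: a small hand-sized instrument for unit
# tests, response constructors, and an independent brute-force scoring
# oracle that recomputes percents straight from raw responses.

rubric4 <- function(name) {
  setNames(as.list(sprintf("Level %d practice for %s.", 1:4, name)),
           as.character(1:4))
}

subcat <- function(id, name, category_id) {
  list(id = id, name = name, category_id = category_id, guidance = "",
       placeholder = TRUE, rubric = rubric4(name))
}

# 2 areas / 3 categories / 5 subcategories
mini_taxonomy <- function() {
  new_taxonomy(
    name = "mini", version = "0.1",
    areas = list(
      list(id = "a", name = "Area A", categories = list(
        list(id = "a.x", name = "Cat X", area_id = "a", subcategories = list(
          subcat("a.x.1", "X one", "a.x"),
          subcat("a.x.2", "X two", "a.x"))),
        list(id = "a.y", name = "Cat Y", area_id = "a", subcategories = list(
          subcat("a.y.1", "Y one", "a.y"))))),
      list(id = "b", name = "Area B", categories = list(
        list(id = "b.z", name = "Cat Z", area_id = "b", subcategories = list(
          subcat("b.z.1", "Z one", "b.z"),
          subcat("b.z.2", "Z two", "b.z"))))))
  )
}

# raw (unvalidated) copy of mini_taxonomy for mutation tests
mini_raw <- function() {
  t <- mini_taxonomy()
  structure(unclass(t), class = "lmt_taxonomy")
}

# assessment answering every subcategory of t with `value`
uniform_assessment <- function(t, value, label = paste0("all-", value)) {
  ids <- taxonomy_index(t)$subcategory_id
  new_assessment(setNames(rep(as.character(value), length(ids)), ids),
                 label = label)
}

# random assessment over t: levels uniform, with given blank/NA rates
random_assessment <- function(t, blank_rate = 0.2, na_rate = 0.1,
                              label = "rnd") {
  ids <- taxonomy_index(t)$subcategory_id
  v <- sample(c("", "NA", "1", "2", "3", "4"), length(ids), replace = TRUE,
              prob = c(blank_rate, na_rate,
                       rep((1 - blank_rate - na_rate) / 4, 4)))
  names(v) <- ids
  new_assessment(v[v != ""], label = label)
}

# a representative mixed assessment (levels, N/A and blanks) over t
sample_assessment <- function(t, label = "lab-A") {
  ids <- taxonomy_index(t)$subcategory_id
  v <- rep(c("4", "2", "NA", "1", ""), length.out = length(ids))
  names(v) <- ids
  new_assessment(v[v != ""], label = label,
                 lab_info = list(name = "Lab A", country = "Wonderland"),
                 date = "2017-05-01", assessor = "external")
}

# every scope percent (overall, areas, categories) as one numeric vector
report_scopes_pcts <- function(a, t, policy = "exclude") {
  r <- score_assessment(a, t, policy)
  c(r$overall$percent, r$per_area$percent, r$per_category$percent)
}

# Independent oracle: percent from raw responses by direct arithmetic,
# written without reference to scope_percent's implementation.
oracle_percent <- function(resp, policy = "exclude") {
  lv <- suppressWarnings(as.integer(resp))
  answered <- !is.na(lv)
  n_blank <- sum(resp == "")
  denom <- if (policy == "exclude") sum(answered) else
    sum(answered) + n_blank
  if (denom == 0) return(NA_real_)
  100 * sum(lv[answered]) / (4 * denom)
}

# oracle for the overall score of an assessment on taxonomy t
oracle_overall <- function(a, t, policy = "exclude") {
  idx <- taxonomy_index(t)
  r <- setNames(rep("", nrow(idx)), idx$subcategory_id)
  r[names(a$responses)] <- a$responses
  oracle_percent(r, policy)
}
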