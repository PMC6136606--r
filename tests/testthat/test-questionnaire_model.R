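test_that("built-in instrument has the published structure", {
  t <- builtin_lmt_s()
  idx <- taxonomy_index(t)
  expect_length(t$areas, 4L)
  expect_identical(length(unique(idx$category_id)), 20L)
  expect_identical(nrow(idx), 98L)

  counts <- table(factor(idx$category_name, levels = unique(idx$category_name)))
  expected <- c(
    "General" = 5, "Personnel health and safety" = 4,
    "Training and competency" = 4,
    "Biosafety manual/Standard operating procedures (SOPs)" = 2,
    "Good lab practices" = 7, "Containment" = 6, "Containment BSL3" = 8,
    "Waste disposal" = 5, "Shipping of infectious substances" = 5,
    "Animal facilities" = 7,
    "Premises" = 7, "Chemical hazard containment" = 6,
    "Chemical security" = 4, "Emergencies" = 4, "Fire hazard" = 4,
    "Electrical" = 4, "Biological safety cabinet (BSC)" = 3,
    "General situation" = 4, "Use of PPE" = 4, "PPE disposal" = 5
  )
  expect_identical(names(counts), names(expected))
  expect_identical(as.vector(counts), as.integer(expected))
  # the Operations area holds 6 categories
  expect_identical(
    length(unique(idx$category_id[idx$area_id == "operations"])), 6L)
  # per-category counts sum to the total
  expect_identical(sum(counts), nrow(idx))
})

test_that("the one published rubric is carried in full", {
  t <- builtin_lmt_s()
  idx <- taxonomy_index(t)
  glove_id <- idx$subcategory_id[idx$subcategory_name ==
                                   "Disposable glove usage"]
  expect_length(glove_id, 1L)
  sc <- taxonomy_subcategory(t, glove_id)
  expect_false(isTRUE(sc$placeholder))
  expect_match(sc$rubric[["1"]], "disposable gloves may be washed and reused")
  expect_match(sc$rubric[["2"]],
               "^Gloves are required whenever handling potentially toxic/infectious materials")
  expect_match(sc$rubric[["4"]], "not reused")
  expect_match(sc$guidance, "don-doff")
  # every other subcategory carries a labelled placeholder rubric
  others <- setdiff(idx$subcategory_id, glove_id)
  for (id in sample(others, 5)) {
    o <- taxonomy_subcategory(t, id)
    expect_true(isTRUE(o$placeholder))
    expect_match(o$rubric[["3"]], "^Placeholder level-3 practice")
  }
})

test_that("load_taxonomy round-trips and accepts the minimal instrument", {
  t <- builtin_lmt_s()
  f <- withr::local_tempfile(fileext = ".json")
  write_taxonomy(t, f)
  expect_identical(load_taxonomy(f), t)

  mini <- new_taxonomy("one", "1", areas = list(
    list(id = "a", name = "A", categories = list(
      list(id = "a.c", name = "C", area_id = "a",
           subcategories = list(subcat("a.c.1", "S", "a.c")))))))
  write_taxonomy(mini, f)
  t2 <- load_taxonomy(f)
  expect_identical(t2, mini)
  expect_identical(nrow(taxonomy_index(t2)), 1L)
})

test_that("loader rejects malformed and invalid schema documents", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", f)
  expect_error(load_taxonomy(f), class = "lmt_parse_error")
  writeLines('{"format": "something-else"}', f)
  expect_error(load_taxonomy(f), "not a taxonomy", class = "lmt_parse_error")

  # subcategory with rubric levels {1,2,3} only: error names node and level
  bad <- mini_raw()
  bad$areas[[1]]$categories[[1]]$subcategories[[1]]$rubric[["4"]] <- NULL
  doc <- list(format = "lmt-taxonomy", schema_version = "1.0",
              name = bad$name, version = bad$version, areas = bad$areas)
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  err <- expect_error(load_taxonomy(f), class = "lmt_validation_error")
  expect_match(conditionMessage(err), "missing-rubric-level")
  expect_match(conditionMessage(err), "level 4")
  expect_match(conditionMessage(err), "subcategories\\[1\\]")
})

test_that("validate_taxonomy reports one finding per violation", {
  expect_identical(nrow(validate_taxonomy(builtin_lmt_s())), 0L)
  expect_identical(nrow(validate_taxonomy(mini_taxonomy())), 0L)

  dup <- mini_raw()
  dup$areas[[1]]$categories[[1]]$subcategories[[2]]$id <- "a.x.1"
  f <- validate_taxonomy(dup)
  expect_identical(f$rule, "duplicate-id")
  expect_match(f$path, "subcategories\\[2\\]")

  dang <- mini_raw()
  dang$areas[[2]]$categories[[1]]$area_id <- "nope"
  f <- validate_taxonomy(dang)
  expect_identical(f$rule, "dangling-reference")

  empty <- mini_raw()
  empty$areas[[1]]$categories[[2]]$subcategories <- list()
  expect_identical(validate_taxonomy(empty)$rule, "empty-category")
})

test_that("validation accepts valid and flags mutated instruments (property)", {
  withr::local_seed(42)
  mutations <- list(
    function(t) { t$areas[[1]]$categories[[1]]$subcategories[[1]]$rubric[["2"]] <- ""; t },
    function(t) { t$areas[[1]]$categories[[1]]$subcategories[[1]]$name <- ""; t },
    function(t) { t$areas[[2]]$categories[[1]]$subcategories[[1]]$category_id <- "ghost"; t },
    function(t) { t$areas[[1]]$id <- t$areas[[2]]$id; t },
    function(t) { t$version <- ""; t },
    function(t) { names(t$areas[[1]]$categories[[2]]$subcategories[[1]]$rubric)[4] <- "5"; t }
  )
  for (i in seq_along(mutations)) {
    expect_identical(nrow(validate_taxonomy(mini_raw())), 0L)
    mutated <- mutations[[i]](mini_raw())
    expect_gt(nrow(validate_taxonomy(mutated)), 0L)
  }
})
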