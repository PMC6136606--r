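test_that("scope_percent matches the optimum-percentage definition", {
  expect_equal(scope_percent(rep("4", 5)), 100)
  expect_equal(scope_percent(c("4", "3", "2", "1")), 62.5)  # 100*10/16
  expect_equal(scope_percent(c("4", "")), 100)
  expect_equal(scope_percent(c("4", ""), "blank_as_zero"), 50)  # 100*4/8
  expect_identical(scope_percent(rep("NA", 4)), NA_real_)
  expect_identical(scope_percent(character()), NA_real_)
  # N/A removed from numerator and denominator under both policies
  expect_equal(scope_percent(c("2", "NA", "NA")), 50)
  expect_equal(scope_percent(c("2", "NA", "NA"), "blank_as_zero"), 50)
  expect_error(scope_percent(c("5")), "illegal response")
  expect_error(score_assessment(uniform_assessment(mini_taxonomy(), 4),
                                mini_taxonomy(), policy = "nope"))
})

test_that("completion counts N/A as completed and blanks as not", {
  t <- builtin_lmt_s()
  ids <- taxonomy_index(t)$subcategory_id
  mixed <- new_assessment(setNames(
    c(rep("4", 50), rep("NA", 48)), ids))
  expect_equal(completion_percent(mixed, t), 100)
  half <- new_assessment(setNames(rep("3", 49), ids[1:49]))
  expect_equal(completion_percent(half, t), 50)
  expect_equal(completion_percent(new_assessment(), t), 0)
})

test_that("confidence bands are lower-inclusive half-open intervals", {
  probes <- c(0, 50, 69.99, 70, 75, 89.99, 90, 95, 100)
  expect_identical(
    confidence_band(probes),
    c("low", "low", "low", "medium", "medium", "medium",
      "reliable", "reliable", "reliable"))
  expect_error(confidence_band(-1), "within")
  expect_error(confidence_band(100.5), "within")
})

test_that("radar bands are the five 20-point rankings, top band closed", {
  probes <- c(0, 19.99, 20, 39.99, 40, 55.6, 59.99, 60, 79.99, 80, 99.99, 100)
  expect_identical(radar_band(probes),
                   c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L, 4L))
  expect_identical(radar_band(NA_real_), NA_integer_)
  expect_error(radar_band(101), "within")
  # non-decreasing in percent
  p <- sort(runif(200, 0, 100))
  expect_true(all(diff(radar_band(p)) >= 0))
})

test_that("score_assessment covers every scope and the printed anchors", {
  t <- builtin_lmt_s()
  r4 <- score_assessment(uniform_assessment(t, 4), t)
  expect_equal(r4$overall$percent, 100)
  expect_identical(nrow(r4$per_area), 4L)
  expect_identical(nrow(r4$per_category), 20L)
  expect_true(all(r4$per_category$percent == 100))
  expect_identical(r4$confidence_band, "reliable")
  expect_identical(r4$overall$radar_band, 4L)

  r1 <- score_assessment(uniform_assessment(t, 1), t)
  expect_equal(r1$overall$percent, 25)

  # only the 13 PPE subcategories answered, all level 4
  idx <- taxonomy_index(t)
  ppe <- idx$subcategory_id[idx$area_id == "ppe"]
  expect_length(ppe, 13L)
  a <- new_assessment(setNames(rep("4", 13), ppe), label = "ppe-only")
  r <- score_assessment(a, t)
  expect_equal(r$per_area$percent[r$per_area$scope_id == "ppe"], 100)
  expect_true(all(is.na(r$per_area$percent[r$per_area$scope_id != "ppe"])))
  expect_equal(r$overall$percent, 100)
  expect_equal(r$completion_percent, 100 * 13 / 98)
  expect_equal(round(r$completion_percent, 1), 13.3)
  expect_identical(r$confidence_band, "low")

  # unknown subcategory is rejected with its id
  bad <- new_assessment(c(ghost.item.1 = "4"))
  expect_error(score_assessment(bad, t), "ghost.item.1",
               class = "lmt_validation_error")
})

test_that("scope counts track answered/applicable/total", {
  t <- mini_taxonomy()
  a <- new_assessment(c(a.x.1 = "4", a.x.2 = "NA", a.y.1 = "2"))
  r <- score_assessment(a, t)
  ov <- r$overall
  expect_identical(ov[, c("answered", "applicable", "total")],
                   data.frame(answered = 3L, applicable = 2L, total = 5L))
  cx <- r$per_category[r$per_category$scope_id == "a.x", ]
  expect_identical(cx$answered, 2L)
  expect_identical(cx$applicable, 1L)
  expect_true(cx$applicable <= cx$answered && cx$answered <= cx$total)
})

test_that("monotonicity: raising one answered level never lowers a scope", {
  withr::local_seed(101)
  t <- builtin_lmt_s()
  for (i in 1:12) {
    a <- random_assessment(t)
    raisable <- names(a$responses)[a$responses %in% c("1", "2", "3")]
    if (length(raisable) == 0) next
    pick <- sample(raisable, 1)
    b <- a
    b$responses[pick] <- as.character(as.integer(a$responses[pick]) + 1L)
    for (policy in c("exclude", "blank_as_zero")) {
      pa <- report_scopes_pcts(a, t, policy)
      pb <- report_scopes_pcts(b, t, policy)
      ok <- !is.na(pa) & !is.na(pb)
      expect_true(all(pb[ok] >= pa[ok] - 1e-12))
    }
  }
})

test_that("N/A neutrality: adding an N/A changes no scope percent", {
  withr::local_seed(202)
  t <- builtin_lmt_s()
  for (i in 1:12) {
    a <- random_assessment(t, blank_rate = 0.4)
    blanks <- setdiff(taxonomy_index(t)$subcategory_id, names(a$responses))
    if (length(blanks) == 0) next
    b <- a
    b$responses[sample(blanks, 1)] <- "NA"
    # exclude policy: N/A at a blank slot is score-neutral
    expect_equal(report_scopes_pcts(b, t, "exclude"),
                 report_scopes_pcts(a, t, "exclude"))
    # blank_as_zero counts blanks in the denominator, so marking one N/A
    # can only remove a zero-contributing item: percents never decrease
    pa <- report_scopes_pcts(a, t, "blank_as_zero")
    pb <- report_scopes_pcts(b, t, "blank_as_zero")
    ok <- !is.na(pa) & !is.na(pb)
    expect_true(all(pb[ok] >= pa[ok] - 1e-12))
    expect_gte(completion_percent(b, t), completion_percent(a, t))
  }
})

test_that("overall equals the applicable-weighted mean of categories and the oracle", {
  withr::local_seed(303)
  t <- builtin_lmt_s()
  for (i in 1:12) {
    a <- random_assessment(t)
    r <- score_assessment(a, t, "exclude")
    pc <- r$per_category
    def <- !is.na(pc$percent)
    weighted <- sum(pc$percent[def] * pc$applicable[def]) /
      sum(pc$applicable[def])
    expect_equal(r$overall$percent, weighted)
    expect_equal(r$overall$percent, oracle_overall(a, t, "exclude"))
    expect_equal(
      score_assessment(a, t, "blank_as_zero")$overall$percent,
      oracle_overall(a, t, "blank_as_zero"))
  }
})

test_that("range: exclude scores lie in [25,100], blank_as_zero in [0,100]", {
  withr::local_seed(404)
  t <- builtin_lmt_s()
  for (i in 1:10) {
    a <- random_assessment(t, blank_rate = runif(1, 0, 0.6),
                           na_rate = runif(1, 0, 0.3))
    pe <- report_scopes_pcts(a, t, "exclude")
    pz <- report_scopes_pcts(a, t, "blank_as_zero")
    expect_true(all(pe[!is.na(pe)] >= 25 & pe[!is.na(pe)] <= 100))
    expect_true(all(pz[!is.na(pz)] >= 0 & pz[!is.na(pz)] <= 100))
  }
})
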