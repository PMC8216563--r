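test_that("the default criterion registry matches the evaluation framework", {
  crit <- default_criteria()
  expect_equal(nrow(crit), 14L)
  expect_equal(crit$id, 1:14)
  expect_false(anyDuplicated(crit$key) > 0)
  expect_equal(crit$key[1], "recruitment")
  expect_match(crit$rationale[1], "recruitment", ignore.case = TRUE)
  expect_equal(crit$key[6], "safe_to_eat")
  expect_equal(
    crit$key[c(7, 10, 13, 14)],
    c("harvest_regulations", "management_plan", "tribes_first_nations",
      "community_grow_harvest")
  )
})

test_that("the four default indices carry the standard weights, vetoes and threshold", {
  defs <- default_index_definitions()
  expect_named(defs, c("ecological_priority", "community_restoration",
                       "community_harvest", "commercial_production"))
  expect_equal(defs$ecological_priority$weights,
               c("1" = 4L, "2" = 3L, "3" = 2L, "4" = 2L))
  expect_equal(defs$community_restoration$weights,
               c("3" = 2L, "5" = 1L, "10" = 2L, "11" = 2L, "12" = 1L,
                 "13" = 1L))
  expect_equal(defs$community_harvest$weights,
               c("3" = 2L, "5" = 1L, "6" = 3L, "7" = 2L, "8" = 1L, "9" = 1L,
                 "13" = 1L, "14" = 1L))
  expect_equal(defs$commercial_production$weights,
               c("3" = 1L, "5" = 2L, "6" = 3L, "8" = 1L, "9" = 1L,
                 "14" = 1L))
  expect_equal(defs$ecological_priority$override, character())
  expect_equal(defs$community_restoration$override, character())
  expect_equal(defs$community_harvest$override, c("6", "7"))
  expect_equal(defs$commercial_production$override, "6")
  for (d in defs) {
    expect_equal(unname(d$threshold["num"] / d$threshold["den"]), 0.5)
    expect_equal(d$max_raw, 2L * sum(d$weights))
  }
})

test_that("index_definition validates weights, overrides and thresholds", {
  expect_error(index_definition("x", c(recruitment = 0)), "positive")
  expect_error(index_definition("x", c(recruitment = 1.5)), "positive integer")
  expect_error(index_definition("x", c(recruitment = 2), override = "growth"),
               "subset")
  expect_error(index_definition("x", c(nope = 1)), "unknown criterion")
  expect_error(index_definition("x", c(recruitment = 1), threshold = 0),
               "threshold")
  d <- index_definition("x", c(recruitment = 2, "3" = 1), threshold = "0.6")
  expect_equal(unname(d$threshold), c(3L, 5L))
  expect_equal(d$max_raw, 6L)
})

test_that("weighted raw sums follow the weights with missing scored as zero", {
  defs <- default_index_definitions()
  eco <- defs$ecological_priority
  all_zero <- stats::setNames(rep(0L, 14), default_criteria()$key)
  expect_equal(weighted_raw_score(all_zero, eco), 0L)
  expect_equal(
    weighted_raw_score(c(recruitment = 2, extinction_risk = 2,
                         mortality = 1, isolation = 0), eco),
    16L
  )
  expect_equal(
    weighted_raw_score(c(recruitment = 2, extinction_risk = NA,
                         mortality = 2, isolation = 2), eco),
    16L
  )
  bad <- index_definition("x", c(recruitment = 1))
  bad$weights <- c("99" = 1L)
  expect_error(weighted_raw_score(c(recruitment = 1), bad), "unknown criterion")
})

test_that("veto criteria trigger on explicit zeros and on missing values", {
  defs <- default_index_definitions()
  keys <- default_criteria()$key
  all_two <- stats::setNames(rep(2L, 14), keys)
  unsafe <- all_two; unsafe["safe_to_eat"] <- 0L
  expect_true(override_triggered(unsafe, defs$community_harvest))
  expect_true(override_triggered(unsafe, defs$commercial_production))
  expect_false(override_triggered(unsafe, defs$ecological_priority))
  expect_false(override_triggered(all_two, defs$community_harvest))
  unknown_safety <- all_two; unknown_safety["safe_to_eat"] <- NA_integer_
  expect_true(override_triggered(unknown_safety, defs$commercial_production))
  no_harvest <- all_two; no_harvest["harvest_regulations"] <- 0L
  expect_true(override_triggered(no_harvest, defs$community_harvest))
  expect_false(override_triggered(no_harvest, defs$commercial_production))
})

test_that("normalized index scores are raw/max with vetoes forcing zero", {
  defs <- default_index_definitions()
  keys <- default_criteria()$key
  expect_equal(
    normalized_index(c(recruitment = 2, extinction_risk = 2, mortality = 2,
                       isolation = 2), defs$ecological_priority),
    1
  )
  expect_equal(
    normalized_index(c(recruitment = 2, extinction_risk = 1, mortality = 0,
                       isolation = 0), defs$ecological_priority),
    11 / 22
  )
  only_safe <- stats::setNames(rep(0L, 14), keys)
  only_safe["safe_to_eat"] <- 2L
  # safety itself is high, so no veto: 3*2 over the maximum of 18
  expect_equal(normalized_index(only_safe, defs$commercial_production), 6 / 18)
  safe_rec <- only_safe
  safe_rec[c("mortality", "hatchery", "growth", "bivalves_farmed",
             "community_grow_harvest")] <- 1L
  expect_equal(normalized_index(safe_rec, defs$commercial_production),
               (1 + 2 + 6 + 1 + 1 + 1) / 18)
  vetoed <- stats::setNames(rep(2L, 14), keys)
  vetoed["safe_to_eat"] <- 0L
  expect_equal(normalized_index(vetoed, defs$community_harvest), 0)
})

test_that("priority classification is exact at the threshold boundary", {
  expect_true(classify_priority(0.5, 0.5))
  expect_true(classify_priority(raw = 11, max_raw = 22, threshold = "1/2"))
  expect_false(classify_priority(raw = 10, max_raw = 22, threshold = "1/2"))
  expect_true(classify_priority(raw = 3, max_raw = 5, threshold = "0.6"))
  expect_false(classify_priority(raw = 299, max_raw = 500, threshold = "0.6"))
  expect_true(classify_priority(1, 1))
  expect_error(classify_priority(0.5, 0), "threshold")
  expect_error(classify_priority(1.2, 0.5), "score")
  expect_error(classify_priority(0.5, 0.5, raw = 1), "both")
})

test_that("index scores stay in [0,1] and attain 1 only for all-high unvetoed records", {
  defs <- default_index_definitions()
  tab <- random_score_table(200, seed = 11)
  res <- score_all(tab, defs)
  expect_true(all(res$score >= 0 & res$score <= 1))
  crit <- default_criteria()
  for (i in seq_len(nrow(res))) {
    def <- defs[[res$index[i]]]
    row <- tab[tab$estuary == res$estuary[i], ]
    v <- as.integer(row[1, crit$key])[as.integer(names(def$weights))]
    all_high <- all(!is.na(v) & v == 2L)
    expect_equal(res$score[i] == 1, all_high && !res$override_applied[i])
  }
})

test_that("raising any single criterion score never lowers any index", {
  defs <- default_index_definitions()
  crit <- default_criteria()
  tab <- random_score_table(60, seed = 21)
  base <- score_all(tab, defs)
  set.seed(22)
  for (i in seq_len(nrow(tab))) {
    j <- sample(1:14, 1)
    k <- crit$key[j]
    v <- tab[[k]][i]
    bumped <- tab
    bumped[[k]][i] <- if (is.na(v)) sample(0:2, 1) else min(v + 1L, 2L)
    res <- score_all(bumped, defs)
    expect_true(all(res$score >= base$score - 1e-12),
                info = sprintf("record %d criterion %s", i, k))
  }
})

test_that("replacing missing scores with explicit zeros changes no index score", {
  defs <- default_index_definitions()
  crit <- default_criteria()
  tab <- random_score_table(80, seed = 31, miss_rate = 0.3)
  filled <- tab
  for (k in crit$key) filled[[k]][is.na(filled[[k]])] <- 0L
  a <- score_all(tab, defs)
  b <- score_all(filled, defs)
  expect_equal(a$score, b$score)
  expect_equal(a$override_applied, b$override_applied)
  expect_equal(a$priority, b$priority)
  # only the missingness bookkeeping may differ
  expect_true(all(b$n_missing_weighted == 0L))
})

test_that("scaling every weight by the same factor leaves scores unchanged", {
  defs <- default_index_definitions()
  tab <- random_score_table(50, seed = 41)
  for (mult in c(2L, 7L)) {
    scaled <- lapply(defs, function(d) {
      index_definition(d$name, d$weights * mult, override = d$override,
                       threshold = d$threshold)
    })
    a <- score_all(tab, defs)
    b <- score_all(tab, scaled)
    expect_equal(a$score, b$score)
    expect_equal(a$priority, b$priority)
  }
})
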