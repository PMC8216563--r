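test_that("Jaccard similarity of priority sets handles all set relations", {
  expect_equal(compare_priority_sets(c("A", "B"), c("A", "B")), 1)
  expect_equal(compare_priority_sets(c("A", "B"), "C"), 0)
  expect_equal(compare_priority_sets(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(compare_priority_sets(character(), character()), 1)
  expect_equal(compare_priority_sets(c("A", "A", "B"), c("B", "A")), 1)
})

test_that("zero-noise resampling reproduces the baseline classification", {
  tab <- generate_table(generator_config(n_estuaries = 15, seed = 4))
  sch <- perturbation_scheme("score_resample", n_draws = 25, seed = 99,
                             flip_probabilities = c("1" = 0, "2" = 0,
                                                    "3" = 0, "none" = 0))
  rep <- run_sensitivity(tab, scheme = sch)
  expect_true(all(rep$priority_frequency %in% c(0, 1)))
  expect_equal(rep$priority_frequency == 1, rep$baseline)
  expect_equal(unname(rep$jaccard_mean), rep(1, 4))

  # zero-range weight jitter is likewise the identity
  sch2 <- perturbation_scheme("weight_jitter", n_draws = 10, seed = 1,
                              weight_jitter_range = 0)
  rep2 <- run_sensitivity(tab, scheme = sch2)
  expect_equal(rep2$priority_frequency == 1, rep2$baseline)
})

test_that("identical seeds give identical stability reports", {
  tab <- generate_table(generator_config(n_estuaries = 12, seed = 8))
  for (kind in c("score_resample", "weight_jitter")) {
    sch <- perturbation_scheme(kind, n_draws = 40, seed = 123)
    a <- run_sensitivity(tab, scheme = sch)
    b <- run_sensitivity(tab, scheme = sch)
    expect_identical(a$priority_frequency, b$priority_frequency)
    expect_identical(a$jaccard_mean, b$jaccard_mean)
  }
})

test_that("leave-one-criterion-out enumerates one rerun per weighted criterion", {
  tab <- generate_table(generator_config(n_estuaries = 10, seed = 6))
  defs <- default_index_definitions()["ecological_priority"]
  sch <- perturbation_scheme("leave_one_criterion_out", seed = 1)
  rep <- run_sensitivity(tab, definitions = defs, scheme = sch)
  expect_equal(rep$n_draws, 4L)  # criteria 1-4 each removed once
  expect_true(all(rep$priority_frequency %in% ((0:4) / 4)))

  # with all four indices: one rerun per weighted criterion of each index
  rep4 <- run_sensitivity(tab, scheme = sch)
  expect_equal(rep4$n_draws, 4L + 6L + 8L + 6L)
})

test_that("a top-scoring estuary with very certain scores is a stable priority", {
  keys <- default_criteria()$key
  rec <- data.frame(estuary = "Apex", region = "OR", stringsAsFactors = FALSE)
  for (k in keys) {
    rec[[k]] <- 2L
    rec[[paste0(k, "_certainty")]] <- 3L
  }
  # with every criterion at 2 (ecological raw 22) and per-criterion flip
  # probability 0.02 moving scores only to the adjacent value 1, even all
  # four criteria flipping at once leaves raw = 11 >= 22/2: the estuary can
  # never fall below the threshold, so its frequency must be 1
  sch <- perturbation_scheme("score_resample", n_draws = 2000, seed = 7,
                             flip_probabilities = c("3" = 0.02))
  rep <- run_sensitivity(score_table(rec), scheme = sch)
  expect_gte(rep$priority_frequency["Apex", "ecological_priority"], 0.9)
  expect_equal(rep$priority_frequency[["Apex", "ecological_priority"]], 1)
})

test_that("raising certainty never loosens priority-set stability", {
  tab <- generate_table(generator_config(n_estuaries = 10, seed = 14))
  crit <- default_criteria()
  low <- high <- tab
  for (k in paste0(crit$key, "_certainty")) {
    low[[k]][!is.na(low[[k]])] <- 1L
    high[[k]][!is.na(high[[k]])] <- 3L
  }
  jac <- function(t, s) {
    mean(run_sensitivity(t, scheme = perturbation_scheme(
      "score_resample", n_draws = 500, seed = s))$jaccard_mean)
  }
  seeds <- 101:120
  j_low <- vapply(seeds, function(s) jac(low, s), numeric(1))
  j_high <- vapply(seeds, function(s) jac(high, s), numeric(1))
  expect_gt(mean(j_high), mean(j_low))
})

test_that("scheme configuration is validated", {
  expect_error(perturbation_scheme(n_draws = 0), "n_draws")
  expect_error(perturbation_scheme(flip_probabilities = c("1" = 1.2)),
               "probabilities")
  expect_error(perturbation_scheme(weight_jitter_range = -1), "jitter")
  expect_error(
    run_sensitivity(
      score_table(data.frame(estuary = character(), region = character()))
    ),
    "no eligible"
  )
})

test_that("stability reports serialize to JSON", {
  tab <- generate_table(generator_config(n_estuaries = 8, seed = 2))
  rep <- run_sensitivity(tab, scheme = perturbation_scheme(n_draws = 10,
                                                           seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_stability_json(rep, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$n_draws, 10L)
  expect_named(js$jaccard_mean, names(rep$jaccard_mean))
})
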