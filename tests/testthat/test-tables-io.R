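test_that("score tables round-trip exactly through CSV", {
  tab <- generate_table(generator_config(n_estuaries = 66, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_table(tab, path)
  back <- read_score_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))

  # custom dialect headers round-trip too
  dial <- score_dialect(
    name_column = "Estuary name", region_column = "Prov/State",
    score_columns = stats::setNames(paste0("Q", 1:14),
                                    default_criteria()$key),
    certainty_suffix = " (certainty)",
    missing_tokens = c("unknown", "", "?")
  )
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_score_table(tab, path2, dialect = dial)
  expect_equal(as.data.frame(read_score_table(path2, dialect = dial)),
               as.data.frame(tab))
  expect_true(any(grepl("unknown", readLines(path2)[2:5])) ||
                !anyNA(tab$recruitment))
})

test_that("missing tokens, star certainties and malformed cells parse as specified", {
  keys <- default_criteria()$key
  hdr <- paste(c("estuary,region", keys,
                 paste0(keys[1], "_certainty")), collapse = ",")
  row1 <- paste(c("A,WA", "unknown", rep("0", 13), "***"), collapse = ",")
  row2 <- paste(c("B,OR", "2", rep("1", 13), "2"), collapse = ",")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(hdr, row1, row2), path)
  tab <- read_score_table(path)
  expect_equal(nrow(tab), 2L)
  expect_true(is.na(tab$recruitment[1]))          # "unknown" token
  expect_equal(tab$recruitment_certainty[1], 3L)  # stars annotate even a missing score
  expect_equal(tab$recruitment[2], 2L)
  expect_equal(tab$recruitment_certainty[2], 2L)

  # a certainty star string parses to its count
  row1b <- paste(c("A,WA", "1", rep("0", 13), "***"), collapse = ",")
  writeLines(c(hdr, row1b), path)
  expect_equal(read_score_table(path)$recruitment_certainty[1], 3L)

  # out-of-scale score cell: error names row and column
  bad <- paste(c("A,WA", "3", rep("0", 13), ""), collapse = ",")
  writeLines(c(hdr, bad), path)
  expect_error(read_score_table(path), "row 1.*recruitment")

  # duplicate estuary names rejected
  writeLines(c(hdr, row2, row2), path)
  expect_error(read_score_table(path), "duplicate")

  # unknown headers warn but are preserved verbatim
  hdr2 <- paste0(hdr, ",recruitment_rationale")
  writeLines(c(hdr2, paste0(row2, ",low spatfall since 2005")), path)
  expect_warning(tab2 <- read_score_table(path), "unknown column")
  expect_equal(tab2$recruitment_rationale, "low spatfall since 2005")
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_score_table(tab2, path3)
  expect_warning(tab3 <- read_score_table(path3), "unknown column")
  expect_equal(as.data.frame(tab3), as.data.frame(tab2))
})

test_that("an empty record list writes a header-only file that reads back empty", {
  empty <- score_table(data.frame(estuary = character(),
                                  region = character()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_table(empty, path)
  expect_length(readLines(path), 1L)
  back <- read_score_table(path)
  expect_equal(nrow(back), 0L)
})

test_that("index configuration files override defaults field by field", {
  defaults <- default_index_definitions()
  expect_equal(read_index_config(NULL), defaults)

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "indices:",
    "  ecological_priority:",
    "    threshold: 0.6"
  ), path)
  cfg <- read_index_config(path)
  expect_equal(unname(cfg$ecological_priority$threshold), c(3L, 5L))
  expect_equal(cfg$ecological_priority$weights,
               defaults$ecological_priority$weights)
  expect_equal(cfg$community_harvest, defaults$community_harvest)

  writeLines(c(
    "indices:",
    "  ecological_priority:",
    "    weights: {recruitment: 0}"
  ), path)
  expect_error(read_index_config(path), "configuration error")

  writeLines(c(
    "indices:",
    "  custom:",
    "    weights: {growth: 2, hatchery: 1}",
    "    override: [growth]",
    "    threshold: '2/3'"
  ), path)
  cfg <- read_index_config(path)
  expect_equal(cfg$custom$weights, c("5" = 1L, "8" = 2L))
  expect_equal(cfg$custom$override, "8")
  expect_equal(unname(cfg$custom$threshold), c(2L, 3L))

  writeLines(c(
    "indices:",
    "  custom:",
    "    weights: {growth: 2}",
    "    override: [hatchery]"
  ), path)
  expect_error(read_index_config(path), "configuration error")
})

test_that("validation flags eligibility, scale, region and certainty problems", {
  keys <- default_criteria()$key
  good <- data.frame(estuary = "A", region = "WA", stringsAsFactors = FALSE)
  for (k in keys) {
    good[[k]] <- 1L
    good[[paste0(k, "_certainty")]] <- 2L
  }
  expect_equal(nrow(validate_table(good)), 0L)

  bad <- good
  bad$estuary <- "B"
  bad$region <- "XX"
  bad$recruitment <- NA_integer_
  bad$extinction_risk <- NA_integer_
  bad$mortality <- NA_integer_
  bad$growth <- 3L
  bad$hatchery_certainty <- NA_integer_
  issues <- validate_table(rbind(good, bad, good))
  expect_s3_class(issues, "oly_validation_issues")
  expect_true(any(issues$severity == "error" &
                    grepl("duplicate", issues$message)))
  expect_true(any(issues$severity == "error" &
                    grepl("0-2 scale", issues$message)))
  expect_true(any(issues$severity == "warning" &
                    grepl("eligib", issues$message)))
  expect_true(any(issues$severity == "warning" &
                    grepl("region 'XX'", issues$message)))
  expect_true(any(issues$severity == "warning" &
                    grepl("certainty annotation", issues$message)))
  expect_true(any(issues$severity == "warning" &
                    grepl("scored as 0", issues$message)))
})
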