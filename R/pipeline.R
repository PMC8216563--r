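#' Eligibility rule on the core ecological criteria
#'
#' Estuaries lacking data on the three core ecological criteria (recruitment
#' limitation, extinction risk, post-settlement mortality) cannot be
#' meaningfully evaluated for conservation aquaculture and are omitted from
#' scoring. The default mode (\code{"all_missing"}) drops a record only when
#' all core criteria are missing; \code{"any_missing"} is the stricter
#' variant, available because published summaries of such screens rarely pin
#' down which reading was used.
#'
#' @param core_criteria Criterion ids (or keys) that carry eligibility;
#'   default ids 1--3.
#' @param mode \code{"all_missing"} (default) or \code{"any_missing"}.
#' @param criteria Criterion registry.
#' @return A list of class \code{eligibility_rule}.
#' @export
eligibility_rule <- function(core_criteria = c(1, 2, 3),
                             mode = c("all_missing", "any_missing"),
                             criteria = default_criteria()) {
  mode <- match.arg(mode)
  ids <- .resolve_criterion_ids(core_criteria, criteria)
  if (!length(ids)) stop("core_criteria must be non-empty", call. = FALSE)
  structure(list(core_criteria = ids, mode = mode),
            class = "eligibility_rule")
}

#' Partition a score table into eligible and excluded records
#'
#' Applies an [eligibility_rule()]: under the default rule a record is
#' excluded iff recruitment, extinction risk and mortality are all missing.
#' Both partitions preserve the input (north-to-south) row order; excluded
#' records are retained for reporting but never scored.
#'
#' @param records A score table.
#' @param rule An [eligibility_rule()].
#' @param criteria Criterion registry.
#' @return A list with score tables \code{eligible} and \code{excluded};
#'   every input row appears in exactly one of the two.
#' @export
filter_eligible <- function(records, rule = eligibility_rule(),
                            criteria = default_criteria()) {
  records <- score_table(records, criteria)
  values <- .score_matrix(records, criteria)
  core <- values[, rule$core_criteria, drop = FALSE]
  excluded <- if (rule$mode == "all_missing") {
    rowSums(is.na(core)) == ncol(core)
  } else {
    rowSums(is.na(core)) > 0L
  }
  list(
    eligible = records[!excluded, , drop = FALSE],
    excluded = records[excluded, , drop = FALSE]
  )
}

#' Rank scored estuaries for one index
#'
#' Orders the result rows of one index descending by score, breaking ties
#' first by fewer missing weighted criteria (a score built on more data ranks
#' above an equal score built on less), then by estuary name — a total,
#' deterministic order.
#'
#' @param results Long results from [score_all()].
#' @param index_name Name of the index to rank.
#' @return The result rows for \code{index_name}, reordered.
#' @export
rank_results <- function(results, index_name) {
  r <- results[results$index == index_name, , drop = FALSE]
  if (!nrow(r) && nrow(results))
    stop("no results for index '", index_name, "'", call. = FALSE)
  # within one index max_raw is constant, so ordering by the effective raw
  # sum (0 under an override) is the exact score order
  eff <- ifelse(r$override_applied, 0L, r$raw)
  r <- r[order(-eff, r$n_missing_weighted, r$estuary), , drop = FALSE]
  rownames(r) <- NULL
  r
}

# exact band tests on integer raw sums: score strictly > 7/10 and < 1;
# score exactly 1
.band_high <- function(raw, max_raw, override) {
  !override & (10L * raw > 7L * max_raw) & (raw < max_raw)
}
.band_max <- function(raw, max_raw, override) {
  !override & raw == max_raw
}

#' Summarize a full prioritization run
#'
#' Runs eligibility filtering and scoring, then tallies the headline
#' quantities: input/eligible/excluded counts; per-index priority counts and
#' (rank-ordered) priority estuary names over the eligible records; per-index
#' score bands (strictly between 0.7 and 1, and exactly 1, computed exactly
#' on the integer raw sums); and, restricted to the estuaries that are
#' priorities under the primary (ecological) index, how many meet each
#' project-type index's threshold.
#'
#' @param records A score table.
#' @param definitions Named list of index definitions.
#' @param rule An [eligibility_rule()].
#' @param primary_index Index defining the priority subset for the
#'   project-type cross-tabulation; defaults to \code{"ecological_priority"}
#'   when present, else the first definition.
#' @param criteria Criterion registry.
#' @return A list of class \code{run_summary}: \code{n_input},
#'   \code{n_eligible}, \code{n_excluded}, \code{excluded} (names),
#'   \code{indices} (per index: \code{n_priority}, \code{priority} names in
#'   rank order, \code{band_high}, \code{band_max}),
#'   \code{primary_index}, and \code{project_type_counts} (named integer
#'   vector over the non-primary indices).
#' @export
summarize_run <- function(records, definitions = default_index_definitions(),
                          rule = eligibility_rule(),
                          primary_index = NULL,
                          criteria = default_criteria()) {
  records <- score_table(records, criteria)
  if (is.null(names(definitions)) && length(definitions))
    names(definitions) <- vapply(definitions, `[[`, "", "name")
  if (is.null(primary_index)) {
    primary_index <- if ("ecological_priority" %in% names(definitions))
      "ecological_priority" else names(definitions)[1L]
  }
  parts <- filter_eligible(records, rule, criteria)
  results <- score_all(parts$eligible, definitions, criteria)
  per_index <- list()
  for (nm in names(definitions)) {
    r <- rank_results(results, nm)
    pr <- r[r$priority, , drop = FALSE]
    per_index[[nm]] <- list(
      n_priority = nrow(pr),
      priority = pr$estuary,
      band_high = sum(.band_high(r$raw, r$max_raw, r$override_applied)),
      band_max = sum(.band_max(r$raw, r$max_raw, r$override_applied))
    )
  }
  prim <- if (length(per_index)) per_index[[primary_index]]$priority else character()
  others <- setdiff(names(definitions), primary_index)
  ptc <- stats::setNames(integer(length(others)), others)
  for (nm in others) {
    r <- results[results$index == nm & results$estuary %in% prim, ,
                 drop = FALSE]
    ptc[nm] <- sum(r$priority)
  }
  structure(
    list(
      n_input = nrow(records),
      n_eligible = nrow(parts$eligible),
      n_excluded = nrow(parts$excluded),
      excluded = parts$excluded$estuary,
      indices = per_index,
      primary_index = primary_index,
      project_type_counts = ptc
    ),
    class = "run_summary"
  )
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Prioritization run summary\n")
  cat("  estuaries: ", x$n_input, " evaluated, ", x$n_eligible,
      " eligible, ", x$n_excluded,
      " excluded (core ecological criteria unscored)\n", sep = "")
  for (nm in names(x$indices)) {
    ix <- x$indices[[nm]]
    cat(sprintf("  %-24s %2d priority estuar%s", nm, ix$n_priority,
                ifelse(ix$n_priority == 1, "y", "ies")))
    cat(sprintf("  [score = 1: %d; 0.7 < score < 1: %d]\n",
                ix$band_max, ix$band_high))
  }
  if (length(x$project_type_counts)) {
    cat("  among the ", x$indices[[x$primary_index]]$n_priority, " ",
        x$primary_index, " estuaries:\n", sep = "")
    for (nm in names(x$project_type_counts))
      cat(sprintf("    %-24s %d at or above threshold\n", nm,
                  x$project_type_counts[[nm]]))
  }
  invisible(x)
}

#' Tabular index-by-estuary report
#'
#' The tabular equivalent of the study-style index figure: one row per
#' eligible estuary in input (north-to-south) order, the four index scores,
#' then the fourteen per-criterion values with missing data kept distinct
#' (\code{NA}, never coerced to 0). Scores are carried at full precision;
#' [write_run_outputs()] renders them to two decimals for display without
#' ever re-classifying on the rounded value.
#'
#' @param records The eligible score table (defines row order).
#' @param results Long results from [score_all()] over the same records.
#' @param definitions Named list of index definitions (defines score-column
#'   order).
#' @param criteria Criterion registry.
#' @return Data frame: \code{estuary}, \code{region}, one numeric score
#'   column per index, one integer column per criterion key.
#' @export
render_index_matrix <- function(records, results,
                                definitions = default_index_definitions(),
                                criteria = default_criteria()) {
  records <- score_table(records, criteria)
  if (is.null(names(definitions)) && length(definitions))
    names(definitions) <- vapply(definitions, `[[`, "", "name")
  out <- data.frame(estuary = records$estuary, region = records$region,
                    stringsAsFactors = FALSE)
  for (nm in names(definitions)) {
    r <- results[results$index == nm, , drop = FALSE]
    out[[nm]] <- r$score[match(records$estuary, r$estuary)]
  }
  for (k in criteria$key) out[[k]] <- records[[k]]
  rownames(out) <- NULL
  out
}

#' Run the full prioritization pipeline
#'
#' One call from score table to classified, ranked, summarized output:
#' validates, filters eligibility, scores every eligible estuary against
#' every index, classifies priorities exactly, and assembles the report
#' matrix and run summary. This is the function the \code{score} CLI verb and
#' most analyses wrap.
#'
#' @param records A score table (or raw data frame in score-table layout).
#' @param definitions Named list of [index_definition()]s.
#' @param rule An [eligibility_rule()].
#' @param criteria Criterion registry.
#' @return An object of class \code{estuary_prioritization}: list with
#'   \code{records}, \code{eligible}, \code{excluded}, \code{results} (long),
#'   \code{matrix} (wide report), \code{summary} ([summarize_run()] output),
#'   \code{definitions}, \code{rule}, \code{issues} (validation warnings).
#'   Methods: \code{print}, \code{summary}, \code{plot}.
#' @examples
#' tab <- generate_benchmark_fixture(seed = 42)
#' fit <- prioritize(tab)
#' fit
#' summary(fit)
#' @export
prioritize <- function(records, definitions = default_index_definitions(),
                       rule = eligibility_rule(),
                       criteria = default_criteria()) {
  if (is.null(names(definitions)) && length(definitions))
    names(definitions) <- vapply(definitions, `[[`, "", "name")
  issues <- validate_table(records, definitions, criteria)
  if (any(issues$severity == "error"))
    stop("score table has validation errors; see validate_table()",
         call. = FALSE)
  records <- score_table(records, criteria)
  parts <- filter_eligible(records, rule, criteria)
  results <- score_all(parts$eligible, definitions, criteria)
  structure(
    list(
      records = records,
      eligible = parts$eligible,
      excluded = parts$excluded,
      results = results,
      matrix = render_index_matrix(parts$eligible, results, definitions,
                                   criteria),
      summary = summarize_run(records, definitions, rule,
                              criteria = criteria),
      definitions = definitions,
      rule = rule,
      issues = issues
    ),
    class = "estuary_prioritization"
  )
}

#' @export
print.estuary_prioritization <- function(x, ...) {
  cat("Conservation-aquaculture prioritization of",
      x$summary$n_input, "estuaries\n")
  cat("  eligible:", x$summary$n_eligible, " excluded:",
      x$summary$n_excluded, "\n")
  for (nm in names(x$summary$indices))
    cat(sprintf("  %-24s %d priority estuar%s\n", nm,
                x$summary$indices[[nm]]$n_priority,
                ifelse(x$summary$indices[[nm]]$n_priority == 1, "y", "ies")))
  cat("Use summary() for bands and project-type counts,",
      "$matrix for the full report.\n")
  invisible(x)
}

#' @export
summary.estuary_prioritization <- function(object, ...) object$summary

#' @export
plot.estuary_prioritization <- function(x, ...) {
  m <- x$matrix
  idx <- names(x$definitions)
  scores <- as.matrix(m[, idx, drop = FALSE])
  n <- nrow(scores)
  if (!n) {
    warning("nothing to plot: no eligible estuaries")
    return(invisible(x))
  }
  op <- graphics::par(mar = c(6, 10, 2, 1))
  on.exit(graphics::par(op))
  # rows plotted top-down = input (north-to-south) order
  graphics::image(
    x = seq_along(idx), y = seq_len(n), z = t(scores[n:1, , drop = FALSE]),
    zlim = c(0, 1), col = grDevices::hcl.colors(32, "YlGnBu", rev = TRUE),
    axes = FALSE, xlab = "", ylab = "", main = "Index scores", ...
  )
  graphics::axis(1, at = seq_along(idx), labels = idx, las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(n), labels = rev(m$estuary), las = 2,
                 cex.axis = 0.6)
  graphics::box()
  invisible(x)
}

#' Write the standard output files of a prioritization run
#'
#' Emits \code{results.csv} (long form, one row per estuary-index pair),
#' \code{matrix.csv} (the report matrix with scores displayed to two
#' decimals and missing criteria as empty cells) and \code{summary.json}.
#' Output is deterministic: identical inputs give byte-identical files. In
#' the JSON matrix, missing criterion scores are \code{null}, never 0.
#'
#' @param fit An [prioritize()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_run_outputs <- function(fit, dir) {
  stopifnot(inherits(fit, "estuary_prioritization"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res_path <- file.path(dir, "results.csv")
  res <- fit$results
  res$score <- sprintf("%.4f", res$score)
  utils::write.csv(res, res_path, row.names = FALSE, fileEncoding = "UTF-8")

  mat_path <- file.path(dir, "matrix.csv")
  m <- fit$matrix
  for (nm in names(fit$definitions)) m[[nm]] <- sprintf("%.2f", m[[nm]])
  for (k in default_criteria()$key)
    if (k %in% names(m)) m[[k]] <- ifelse(is.na(m[[k]]), "", m[[k]])
  utils::write.csv(m, mat_path, row.names = FALSE, fileEncoding = "UTF-8")

  sum_path <- file.path(dir, "summary.json")
  s <- fit$summary
  json <- list(
    n_input = s$n_input, n_eligible = s$n_eligible,
    n_excluded = s$n_excluded, excluded = as.list(s$excluded),
    indices = lapply(s$indices, function(ix) list(
      n_priority = ix$n_priority, priority = as.list(ix$priority),
      band_high = ix$band_high, band_max = ix$band_max
    )),
    primary_index = s$primary_index,
    project_type_counts = as.list(s$project_type_counts),
    matrix = lapply(seq_len(nrow(fit$matrix)), function(i) {
      row <- as.list(fit$matrix[i, , drop = FALSE])
      lapply(row, function(v) if (length(v) == 1L && is.na(v)) NULL else v)
    })
  )
  jsonlite::write_json(json, sum_path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(c(results = res_path, matrix = mat_path, summary = sum_path))
}
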