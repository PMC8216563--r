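# Core index algebra. All classification arithmetic is integer: raw weighted
# sums, maxima, and cross-multiplied threshold comparisons. The numeric
# 'score' column is derived for display and downstream numerics only; it never
# feeds a classification decision.

# Vectorized scoring of a value matrix (columns named by criterion id,
# NA = missing) against one index definition.
.score_core <- function(values, definition) {
  ids <- names(definition$weights)
  miss <- setdiff(ids, colnames(values))
  if (length(miss))
    stop("index '", definition$name, "' references unknown criterion id(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  v <- values[, ids, drop = FALSE]
  n_missing <- as.integer(rowSums(is.na(v)))
  v0 <- v
  v0[is.na(v0)] <- 0L
  raw <- as.integer(v0 %*% definition$weights)
  if (length(definition$override)) {
    ov <- v0[, definition$override, drop = FALSE]
    override <- rowSums(ov == 0L) > 0L
  } else {
    override <- rep(FALSE, nrow(v))
  }
  eff_raw <- ifelse(override, 0L, raw)
  priority <- !override &
    .ge_rational(raw, definition$max_raw, definition$threshold)
  list(
    raw = raw,
    max_raw = definition$max_raw,
    score = eff_raw / definition$max_raw,
    override_applied = override,
    priority = priority,
    n_missing_weighted = n_missing
  )
}

#' Raw weighted sum of an estuary's criterion scores
#'
#' Sums \code{weight * value} over the index's weighted criteria. A missing
#' (\code{NA}) criterion contributes zero, per the conservative missing-data
#' rule; certainty annotations never enter the sum.
#'
#' @param record A single estuary record: a one-row score table, or a vector
#'   named by criterion key or id with values 0, 1, 2 or \code{NA}.
#' @param definition An [index_definition()].
#' @param criteria Criterion registry.
#' @return Non-negative integer raw sum (at most \code{definition$max_raw}).
#' @examples
#' defs <- default_index_definitions()
#' weighted_raw_score(
#'   c(recruitment = 2, extinction_risk = 2, mortality = 1, isolation = 0),
#'   defs$ecological_priority
#' ) # 4*2 + 3*2 + 2*1 + 2*0 = 16
#' @export
weighted_raw_score <- function(record, definition,
                               criteria = default_criteria()) {
  v <- .record_values(record, criteria)
  .score_core(matrix(v, nrow = 1L, dimnames = list(NULL, names(v))),
              definition)$raw
}

#' Does a veto criterion force this index to zero?
#'
#' TRUE when any of the definition's override (veto) criteria has an effective
#' value of 0 for the record — either an explicit 0 score or a missing value,
#' which scores as 0. For example, an estuary where shellfish are unsafe to
#' eat is vetoed for both community harvest and commercial production, no
#' matter how well it scores otherwise. Indices without override criteria
#' never trigger.
#'
#' @inheritParams weighted_raw_score
#' @return Logical flag.
#' @export
override_triggered <- function(record, definition,
                               criteria = default_criteria()) {
  v <- .record_values(record, criteria)
  .score_core(matrix(v, nrow = 1L, dimnames = list(NULL, names(v))),
              definition)$override_applied
}

#' Normalized index score in [0, 1]
#'
#' The raw weighted sum divided by the maximum possible sum (every weighted
#' criterion at 2), or exactly 0 when an override criterion vetoes the record.
#' A score of 1 is attained only by a record scoring 2 on every weighted
#' criterion with no veto.
#'
#' @inheritParams weighted_raw_score
#' @return Numeric score in \eqn{[0, 1]}. Classification against thresholds
#'   should use [classify_priority()] (exact rational comparison) rather than
#'   comparing this floating-point value.
#' @examples
#' defs <- default_index_definitions()
#' normalized_index(
#'   c(recruitment = 2, extinction_risk = 2, mortality = 2, isolation = 2),
#'   defs$ecological_priority
#' ) # 1
#' @export
normalized_index <- function(record, definition,
                             criteria = default_criteria()) {
  v <- .record_values(record, criteria)
  .score_core(matrix(v, nrow = 1L, dimnames = list(NULL, names(v))),
              definition)$score
}

#' Exact priority classification
#'
#' An estuary is a priority for an index when its score meets or exceeds the
#' threshold. The comparison is exact at the boundary: a raw/max ratio equal
#' to the threshold (e.g. 11/22 against 0.50) classifies as priority. Supply
#' \code{raw} and \code{max_raw} to compare by integer cross-multiplication;
#' a bare numeric \code{score} is converted through its decimal representation
#' to an exact rational first, so no binary-float \code{>=} is ever used.
#'
#' @param score Numeric score in \eqn{[0, 1]} (ignored when \code{raw} and
#'   \code{max_raw} are given).
#' @param threshold Threshold in \eqn{(0, 1]}: number, string (\code{"0.50"},
#'   \code{"1/2"}) or exact rational.
#' @param raw,max_raw Optional integer numerator and denominator of the score.
#' @return Logical flag.
#' @examples
#' classify_priority(0.5, 0.5)            # TRUE, boundary inclusive
#' classify_priority(raw = 11, max_raw = 22, threshold = "1/2")  # TRUE
#' classify_priority(raw = 10, max_raw = 22, threshold = "1/2")  # FALSE
#' @export
classify_priority <- function(score, threshold = "0.50",
                              raw = NULL, max_raw = NULL) {
  thr <- .as_rational(threshold)
  tv <- .rational_value(thr)
  if (tv <= 0 || tv > 1)
    stop("'threshold' must lie in (0, 1]", call. = FALSE)
  if (!is.null(raw) || !is.null(max_raw)) {
    if (is.null(raw) || is.null(max_raw))
      stop("supply both 'raw' and 'max_raw' or neither", call. = FALSE)
    stopifnot(max_raw > 0, raw >= 0)
    return(.ge_rational(as.integer(raw), as.integer(max_raw), thr))
  }
  s <- .as_rational(score)
  sv <- .rational_value(s)
  if (sv < 0 || sv > 1) stop("'score' must lie in [0, 1]", call. = FALSE)
  .ge_rational(s["num"], s["den"], thr)
}

#' Score every estuary against every index
#'
#' Computes one result row per (estuary, index) pair: the integer raw
#' weighted sum, its maximum, the normalized score, whether a veto criterion
#' forced the score to zero, the exact priority classification, and how many
#' weighted criteria were missing (missing scores count as zero, so this
#' column quantifies how conservative each score is).
#'
#' @param records A score table (see [score_table()]), normally already
#'   filtered with [filter_eligible()].
#' @param definitions Named list of [index_definition()] objects; defaults to
#'   the four standard indices.
#' @param criteria Criterion registry.
#' @return A data frame of class \code{oly_index_results} in long form with
#'   columns \code{estuary}, \code{index}, \code{raw}, \code{max_raw},
#'   \code{score}, \code{eligible}, \code{override_applied}, \code{priority},
#'   \code{n_missing_weighted}. Rows are ordered by input record, then by
#'   definition order.
#' @examples
#' tab <- generate_table(generator_config(n_estuaries = 5, seed = 1))
#' head(score_all(tab))
#' @export
score_all <- function(records, definitions = default_index_definitions(),
                      criteria = default_criteria()) {
  records <- score_table(records, criteria)
  if (is.null(names(definitions)) && length(definitions))
    names(definitions) <- vapply(definitions, `[[`, "", "name")
  values <- .score_matrix(records, criteria)
  out <- vector("list", length(definitions))
  for (i in seq_along(definitions)) {
    def <- definitions[[i]]
    sc <- .score_core(values, def)
    out[[i]] <- data.frame(
      estuary = records$estuary,
      index = rep(def$name, nrow(records)),
      raw = sc$raw,
      max_raw = rep(sc$max_raw, nrow(records)),
      score = sc$score,
      eligible = rep(TRUE, nrow(records)),
      override_applied = sc$override_applied,
      priority = sc$priority,
      n_missing_weighted = sc$n_missing_weighted,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(
      estuary = character(), index = character(), raw = integer(),
      max_raw = integer(), score = numeric(), eligible = logical(),
      override_applied = logical(), priority = logical(),
      n_missing_weighted = integer(), stringsAsFactors = FALSE
    )
  } else {
    # interleave so all indices of a record are adjacent, in input order
    res <- res[order(match(res$estuary, records$estuary),
                     match(res$index, names(definitions))), , drop = FALSE]
  }
  rownames(res) <- NULL
  class(res) <- c("oly_index_results", "data.frame")
  res
}
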