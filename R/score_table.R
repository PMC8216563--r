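#' Construct or validate an estuary score table
#'
#' The score table is the package's central container: one row per estuary
#' (sub-basins of large systems such as the Salish Sea or San Francisco Bay
#' are independent rows, never aggregated), with an ordinal 0/1/2 score and an
#' optional 1--3 certainty level for each of the fourteen criteria. A missing
#' score is \code{NA}: it scores as zero in every index (the conservative
#' missing-data rule) but remains distinguishable from an assigned 0, which
#' matters for eligibility filtering and for reporting.
#'
#' @param x A data frame with columns \code{estuary}, \code{region},
#'   optionally \code{parent_system}, one integer column per criterion key
#'   (values 0, 1, 2 or \code{NA}), and optionally
#'   \code{<key>_certainty} columns (values 1, 2, 3 or \code{NA}).
#' @param criteria Criterion registry; defaults to [default_criteria()].
#' @return \code{x}, completed (absent certainty columns filled with
#'   \code{NA}, absent \code{parent_system} with \code{NA}) and classed
#'   \code{oly_score_table}.
#' @details Region codes follow the study range: \code{BCC} (British
#'   Columbia), \code{WA}, \code{OR}, \code{CA}, \code{BCM} (Baja
#'   California). Unknown codes are permitted here but flagged by
#'   [validate_table()].
#' @examples
#' tab <- data.frame(estuary = "Synth Cove", region = "WA")
#' for (k in default_criteria()$key) tab[[k]] <- 2L
#' tab <- score_table(tab)
#' @export
score_table <- function(x, criteria = default_criteria()) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"estuary" %in% names(x))
    stop("score table must have an 'estuary' column", call. = FALSE)
  if (nrow(x) && anyDuplicated(x$estuary))
    stop("duplicate estuary names: ",
         paste(unique(x$estuary[duplicated(x$estuary)]), collapse = ", "),
         call. = FALSE)
  if (!"region" %in% names(x)) x$region <- rep(NA_character_, nrow(x))
  if (!"parent_system" %in% names(x))
    x$parent_system <- rep(NA_character_, nrow(x))
  x$estuary <- as.character(x$estuary)
  x$region <- as.character(x$region)
  x$parent_system <- as.character(x$parent_system)
  for (k in criteria$key) {
    if (!k %in% names(x)) x[[k]] <- rep(NA_integer_, nrow(x))
    v <- x[[k]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & (!v %in% c(0, 1, 2))))
      stop("scores for '", k, "' must be 0, 1, 2 or NA", call. = FALSE)
    x[[k]] <- as.integer(v)
    ck <- paste0(k, "_certainty")
    if (!ck %in% names(x)) x[[ck]] <- rep(NA_integer_, nrow(x))
    cv <- x[[ck]]
    if (is.character(cv)) cv <- suppressWarnings(as.numeric(cv))
    if (any(!is.na(cv) & (!cv %in% c(1, 2, 3))))
      stop("certainty for '", k, "' must be 1, 2, 3 or NA", call. = FALSE)
    x[[ck]] <- as.integer(cv)
  }
  ord <- c("estuary", "region", "parent_system",
           criteria$key, paste0(criteria$key, "_certainty"))
  extra <- setdiff(names(x), ord)
  x <- x[, c(ord, extra), drop = FALSE]
  rownames(x) <- NULL
  class(x) <- unique(c("oly_score_table", class(x)))
  x
}

# n x 14 integer matrix of criterion values, columns named by criterion id
.score_matrix <- function(records, criteria = default_criteria()) {
  m <- as.matrix(as.data.frame(records)[, criteria$key, drop = FALSE])
  storage.mode(m) <- "integer"
  colnames(m) <- as.character(criteria$id)
  rownames(m) <- records$estuary
  m
}

.certainty_matrix <- function(records, criteria = default_criteria()) {
  m <- as.matrix(
    as.data.frame(records)[, paste0(criteria$key, "_certainty"), drop = FALSE]
  )
  storage.mode(m) <- "integer"
  colnames(m) <- as.character(criteria$id)
  rownames(m) <- records$estuary
  m
}

# Coerce a single record (one-row score table, named vector or named list,
# names being criterion keys or ids) to an integer vector named by id.
.record_values <- function(record, criteria = default_criteria()) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1L)
      stop("expected a single record (one row)", call. = FALSE)
    if (!all(criteria$key %in% names(record)))
      record <- score_table(record, criteria)[1L, ]
    return(.score_matrix(record, criteria)[1L, ])
  }
  if (is.list(record)) record <- unlist(record)
  if (is.null(names(record)))
    stop("record must be named by criterion key or id", call. = FALSE)
  ids <- .resolve_criterion_ids(names(record), criteria)
  out <- stats::setNames(rep(NA_integer_, nrow(criteria)), as.character(criteria$id))
  v <- as.integer(record)
  if (any(!is.na(v) & !v %in% c(0L, 1L, 2L)))
    stop("criterion scores must be 0, 1, 2 or NA", call. = FALSE)
  out[ids] <- v
  out
}

#' @export
print.oly_score_table <- function(x, n = 10L, ...) {
  crit <- default_criteria()
  cat("Estuary score table: ", nrow(x), " record(s), ",
      sum(is.na(.score_matrix(x, crit))), " missing score(s)\n", sep = "")
  utils::print.data.frame(
    utils::head(as.data.frame(x)[, c("estuary", "region", crit$key)], n)
  )
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more record(s)\n", sep = "")
  invisible(x)
}
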