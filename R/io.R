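#' Column-layout dialect for score-table files
#'
#' Score tables circulate as delimited text with varying headers (the study's
#' scoring spreadsheet, regional exports, hand-edited CSVs). A dialect maps
#' the package's canonical criterion keys onto the file's column headers so
#' foreign layouts can be ingested without code changes.
#'
#' @param name_column,region_column,parent_column Headers of the estuary
#'   name, region code and parent-system columns.
#' @param score_columns Named character vector mapping each criterion key to
#'   its column header; default: the keys themselves.
#' @param certainty_suffix Suffix appended to a score header to form its
#'   certainty column header.
#' @param missing_tokens Cell values parsed as a missing score. The first
#'   token is used when writing missing values (default: the empty cell).
#' @param criteria Criterion registry.
#' @return A list of class \code{score_dialect}.
#' @export
score_dialect <- function(name_column = "estuary",
                          region_column = "region",
                          parent_column = "parent_system",
                          score_columns = NULL,
                          certainty_suffix = "_certainty",
                          missing_tokens = c("", "unknown", "NA", "?"),
                          criteria = default_criteria()) {
  if (is.null(score_columns))
    score_columns <- stats::setNames(criteria$key, criteria$key)
  if (!all(criteria$key %in% names(score_columns)))
    stop("score_columns must map all ", nrow(criteria), " criterion keys",
         call. = FALSE)
  score_columns <- score_columns[criteria$key]
  if (anyDuplicated(score_columns))
    stop("score_columns headers must be distinct", call. = FALSE)
  if (!length(missing_tokens))
    stop("at least one missing token is required", call. = FALSE)
  structure(
    list(
      name_column = name_column, region_column = region_column,
      parent_column = parent_column, score_columns = score_columns,
      certainty_suffix = certainty_suffix,
      missing_tokens = as.character(missing_tokens)
    ),
    class = "score_dialect"
  )
}

.parse_certainty_cell <- function(cell) {
  cell <- trimws(cell)
  if (!nzchar(cell) || cell %in% c("NA", "na")) return(NA_integer_)
  if (grepl("^\\*{1,3}$", cell)) return(nchar(cell))
  if (cell %in% c("1", "2", "3")) return(as.integer(cell))
  stop("unparseable certainty value '", cell, "'", call. = FALSE)
}

#' Read an estuary score table from delimited text
#'
#' Parses a CSV score table (UTF-8, comma-separated, header row) into a
#' [score_table()]. Score cells must be 0, 1 or 2, or one of the dialect's
#' missing tokens; certainty cells may be integers 1--3 or star strings
#' (\code{*} to \code{***}). Unrecognized columns are preserved verbatim
#' (with a warning) and round-trip through [write_score_table()]; free-text
#' rationale or source columns are therefore carried along but never
#' interpreted.
#'
#' @param path Path to a CSV file.
#' @param dialect A [score_dialect()].
#' @param criteria Criterion registry.
#' @return A score table; \code{read_score_table(write_score_table(x))}
#'   reproduces \code{x} exactly.
#' @export
read_score_table <- function(path, dialect = score_dialect(),
                             criteria = default_criteria()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(), fileEncoding = "UTF-8")
  if (!dialect$name_column %in% names(raw))
    stop("missing estuary name column '", dialect$name_column, "'",
         call. = FALSE)
  cert_headers <- stats::setNames(
    paste0(dialect$score_columns, dialect$certainty_suffix),
    names(dialect$score_columns)
  )
  known <- c(dialect$name_column, dialect$region_column, dialect$parent_column,
             dialect$score_columns, cert_headers)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("unknown column header(s) preserved verbatim: ",
            paste(unknown, collapse = ", "), call. = FALSE)

  out <- data.frame(estuary = trimws(raw[[dialect$name_column]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$estuary))
    stop("duplicate estuary name(s): ",
         paste(unique(out$estuary[duplicated(out$estuary)]), collapse = ", "),
         call. = FALSE)
  out$region <- if (dialect$region_column %in% names(raw))
    trimws(raw[[dialect$region_column]]) else NA_character_
  out$parent_system <- if (dialect$parent_column %in% names(raw)) {
    p <- trimws(raw[[dialect$parent_column]])
    ifelse(nzchar(p), p, NA_character_)
  } else NA_character_

  for (k in criteria$key) {
    hdr <- dialect$score_columns[[k]]
    if (hdr %in% names(raw)) {
      cells <- trimws(raw[[hdr]])
      vals <- rep(NA_integer_, length(cells))
      is_missing <- cells %in% dialect$missing_tokens
      ok <- is_missing | cells %in% c("0", "1", "2")
      if (any(!ok)) {
        i <- which(!ok)[1L]
        stop("unparseable score '", cells[i], "' at row ", i,
             ", column '", hdr, "' (expected 0, 1, 2 or a missing token)",
             call. = FALSE)
      }
      vals[!is_missing] <- as.integer(cells[!is_missing])
      out[[k]] <- vals
    } else {
      out[[k]] <- NA_integer_
    }
    chdr <- cert_headers[[k]]
    out[[paste0(k, "_certainty")]] <- if (chdr %in% names(raw)) {
      vapply(raw[[chdr]], .parse_certainty_cell, integer(1L), USE.NAMES = FALSE)
    } else NA_integer_
  }
  for (u in unknown) out[[u]] <- raw[[u]]
  score_table(out, criteria)
}

#' Write an estuary score table as delimited text
#'
#' The inverse of [read_score_table()]: canonical columns in criterion-id
#' order, missing scores as the dialect's first missing token (the empty cell
#' by default), certainty always as integers 1--3. Any extra columns carried
#' on the table are appended verbatim.
#'
#' @param records A score table.
#' @param path Output file path.
#' @param dialect A [score_dialect()].
#' @param criteria Criterion registry.
#' @return \code{path}, invisibly.
#' @export
write_score_table <- function(records, path, dialect = score_dialect(),
                              criteria = default_criteria()) {
  records <- score_table(records, criteria)
  miss_tok <- dialect$missing_tokens[1L]
  out <- data.frame(row.names = seq_len(nrow(records)))
  out[[dialect$name_column]] <- records$estuary
  out[[dialect$region_column]] <- ifelse(is.na(records$region), "",
                                         records$region)
  out[[dialect$parent_column]] <- ifelse(is.na(records$parent_system), "",
                                         records$parent_system)
  for (k in criteria$key) {
    v <- records[[k]]
    out[[dialect$score_columns[[k]]]] <- ifelse(is.na(v), miss_tok,
                                                as.character(v))
    cv <- records[[paste0(k, "_certainty")]]
    out[[paste0(dialect$score_columns[[k]], dialect$certainty_suffix)]] <-
      ifelse(is.na(cv), "", as.character(cv))
  }
  canonical <- c("estuary", "region", "parent_system", criteria$key,
                 paste0(criteria$key, "_certainty"))
  for (u in setdiff(names(records), canonical)) out[[u]] <- records[[u]]
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read index definitions from a YAML/JSON configuration
#'
#' Reads a configuration document with entries
#' \code{indices.<name>.weights} (criterion key or id to positive integer),
#' \code{indices.<name>.override} and \code{indices.<name>.threshold}. Any
#' index or field absent from the document falls back to
#' [default_index_definitions()]; an absent or \code{NULL} path returns the
#' defaults unchanged. Thresholds written as decimal text (\code{0.50}) are
#' converted to exact rationals at parse time so boundary classification
#' stays exact.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file, or \code{NULL}.
#' @param criteria Criterion registry.
#' @return Named list of [index_definition()] objects.
#' @export
read_index_config <- function(path = NULL, criteria = default_criteria()) {
  defs <- default_index_definitions()
  if (is.null(path) || !file.exists(path)) return(defs)
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(cfg$indices)) cfg$indices else cfg
  if (is.null(entries) || !length(entries)) return(defs)
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop("configuration error: indices must be named", call. = FALSE)
  for (nm in names(entries)) {
    e <- entries[[nm]]
    base <- defs[[nm]]
    weights <- if (!is.null(e$weights)) {
      unlist(e$weights)
    } else if (!is.null(base)) {
      base$weights
    } else {
      stop("configuration error: new index '", nm, "' needs weights",
           call. = FALSE)
    }
    override <- if (!is.null(e$override)) {
      as.character(unlist(e$override))
    } else if (!is.null(base)) base$override else character()
    threshold <- if (!is.null(e$threshold)) {
      e$threshold
    } else if (!is.null(base)) base$threshold else "0.50"
    defs[[nm]] <- tryCatch(
      index_definition(nm, weights, override = override,
                       threshold = threshold, criteria = criteria),
      error = function(cnd) {
        stop("configuration error in index '", nm, "': ",
             conditionMessage(cnd), call. = FALSE)
      }
    )
  }
  defs
}

#' Validate a score table against the scoring rules
#'
#' Collects problems instead of stopping at the first one. Errors (which
#' block scoring): duplicate estuary names, score values off the 0/1/2 scale,
#' certainty values off the 1--3 scale. Warnings: missing values among the
#' weighted criteria of an active index (scored conservatively as 0), all
#' three core ecological criteria missing (the record will be dropped by
#' eligibility filtering), region codes outside the known range, and
#' non-missing scores lacking a certainty annotation.
#'
#' @param records A score table or a raw data frame in score-table layout.
#' @param definitions Named list of index definitions whose weighted criteria
#'   are checked for missingness.
#' @param criteria Criterion registry.
#' @return A data frame of class \code{oly_validation_issues} with columns
#'   \code{severity} (\code{"error"}/\code{"warning"}), \code{estuary},
#'   \code{criterion} (id or \code{NA}) and \code{message}; zero rows for a
#'   fully scored, fully annotated, valid table.
#' @export
validate_table <- function(records,
                           definitions = default_index_definitions(),
                           criteria = default_criteria()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  issues <- list()
  add <- function(severity, estuary, criterion, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, estuary = estuary,
      criterion = if (is.null(criterion)) NA_integer_ else as.integer(criterion),
      message = message, stringsAsFactors = FALSE
    )
  }
  if ("estuary" %in% names(records)) {
    for (d in unique(records$estuary[duplicated(records$estuary)]))
      add("error", d, NULL, "duplicate estuary name")
  } else {
    add("error", NA_character_, NULL, "missing 'estuary' column")
    records$estuary <- paste0("row_", seq_len(nrow(records)))
  }
  known_regions <- c("BCC", "WA", "OR", "CA", "BCM")
  for (i in seq_len(nrow(records))) {
    nm <- records$estuary[i]
    reg <- if ("region" %in% names(records)) records$region[i] else NA
    if (!is.na(reg) && !reg %in% known_regions)
      add("warning", nm, NULL,
          paste0("region '", reg, "' outside known codes ",
                 paste(known_regions, collapse = "/")))
    vals <- rep(NA_integer_, nrow(criteria))
    for (j in seq_len(nrow(criteria))) {
      k <- criteria$key[j]
      v <- if (k %in% names(records)) records[[k]][i] else NA
      if (is.character(v)) v <- suppressWarnings(as.numeric(v))
      if (!is.na(v) && !v %in% c(0, 1, 2)) {
        add("error", nm, criteria$id[j],
            paste0("score ", v, " for '", k, "' outside the 0-2 scale"))
        v <- NA
      }
      vals[j] <- as.integer(v)
      ck <- paste0(k, "_certainty")
      cv <- if (ck %in% names(records)) records[[ck]][i] else NA
      if (is.character(cv)) cv <- suppressWarnings(as.numeric(cv))
      if (!is.na(cv) && !cv %in% c(1, 2, 3))
        add("error", nm, criteria$id[j],
            paste0("certainty ", cv, " for '", k, "' outside the 1-3 scale"))
      if (!is.na(vals[j]) && is.na(cv))
        add("warning", nm, criteria$id[j],
            paste0("score for '", k, "' lacks a certainty annotation"))
    }
    if (all(is.na(vals[1:3])))
      add("warning", nm, NULL,
          paste0("core ecological criteria 1-3 all missing: record fails ",
                 "eligibility and will be omitted from scoring"))
    for (def in definitions) {
      ids <- as.integer(names(def$weights))
      n_miss <- sum(is.na(vals[match(ids, criteria$id)]))
      if (n_miss > 0L)
        add("warning", nm, NULL,
            paste0(n_miss, " weighted criterion score(s) missing for index '",
                   def$name, "' (scored as 0)"))
    }
  }
  out <- if (length(issues)) do.call(rbind, issues) else data.frame(
    severity = character(), estuary = character(), criterion = integer(),
    message = character(), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("oly_validation_issues", "data.frame")
  out
}

#' @export
print.oly_validation_issues <- function(x, ...) {
  if (!nrow(x)) {
    cat("No validation issues.\n")
    return(invisible(x))
  }
  cat(sum(x$severity == "error"), "error(s),",
      sum(x$severity == "warning"), "warning(s)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %s%s: %s\n", x$severity[i],
                ifelse(is.na(x$estuary[i]), "<table>", x$estuary[i]),
                ifelse(is.na(x$criterion[i]), "",
                       paste0(" (criterion ", x$criterion[i], ")")),
                x$message[i]))
  }
  invisible(x)
}
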