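# Priority-set stability machinery. The scoring framework annotates every
# expert score with a 1-3 certainty level but prescribes no quantitative
# error model; this module supplies one as clearly labelled configuration:
# scores may be resampled to ordinally adjacent values with certainty-graded
# probabilities, weights jittered by one integer step, or criteria removed
# one at a time, and the stability of the resulting priority sets is
# summarized.

#' Define a perturbation scheme for sensitivity analysis
#'
#' Three perturbation kinds are supported. \code{"score_resample"}: each
#' non-missing criterion score is replaced, with a probability set by its
#' certainty level, by an ordinally adjacent value (0 and 2 move to 1; 1
#' moves up or down with equal probability); missing values are never
#' resampled. \code{"weight_jitter"}: each index weight is shifted by an
#' integer step drawn uniformly from \code{-weight_jitter_range} to
#' \code{+weight_jitter_range}, floored at 1 so exact rational scoring stays
#' valid. \code{"leave_one_criterion_out"}: deterministic — each weighted
#' criterion of each index is removed in turn and the maximum rescaled
#' (\code{n_draws} is ignored).
#'
#' @param kind One of \code{"score_resample"}, \code{"weight_jitter"},
#'   \code{"leave_one_criterion_out"}.
#' @param n_draws Number of Monte-Carlo draws (\eqn{\ge 1}).
#' @param seed Integer seed; identical seeds give identical reports.
#' @param flip_probabilities Named probabilities of resampling a score, by
#'   certainty level \code{"1"}, \code{"2"}, \code{"3"} and \code{"none"}
#'   (unannotated scores). The defaults (0.30, 0.10, 0.02, 0.30) are
#'   configuration constants that order the certainty levels, not findings.
#' @param weight_jitter_range Maximum integer step for weight jitter.
#' @return A list of class \code{perturbation_scheme}.
#' @export
perturbation_scheme <- function(kind = c("score_resample", "weight_jitter",
                                         "leave_one_criterion_out"),
                                n_draws = 500L, seed = 1L,
                                flip_probabilities = c("1" = 0.30, "2" = 0.10,
                                                       "3" = 0.02,
                                                       "none" = 0.30),
                                weight_jitter_range = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(n_draws) || length(n_draws) != 1L || n_draws < 1)
    stop("configuration error: n_draws must be >= 1", call. = FALSE)
  fp <- c("1" = 0.30, "2" = 0.10, "3" = 0.02, "none" = 0.30)
  fp[names(flip_probabilities)] <- flip_probabilities
  if (any(fp < 0 | fp > 1))
    stop("configuration error: flip probabilities must lie in [0, 1]",
         call. = FALSE)
  if (weight_jitter_range < 0)
    stop("configuration error: weight_jitter_range must be >= 0",
         call. = FALSE)
  structure(
    list(kind = kind, n_draws = as.integer(n_draws), seed = as.integer(seed),
         flip_probabilities = fp,
         weight_jitter_range = as.integer(weight_jitter_range)),
    class = "perturbation_scheme"
  )
}

#' Jaccard similarity of two priority sets
#'
#' \eqn{|a \cap b| / |a \cup b|}; defined as 1 when both sets are empty
#' (two runs that both select nothing agree perfectly).
#'
#' @param a,b Character vectors of estuary names (treated as sets).
#' @return Similarity in \eqn{[0, 1]}.
#' @examples
#' compare_priority_sets(c("A", "B", "C"), c("B", "C", "D")) # 0.5
#' @export
compare_priority_sets <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

# priority flags (logical matrix estuary x index) for a value matrix
.priority_flags <- function(values, definitions) {
  out <- matrix(FALSE, nrow(values), length(definitions),
                dimnames = list(rownames(values), names(definitions)))
  for (nm in names(definitions))
    out[, nm] <- .score_core(values, definitions[[nm]])$priority
  out
}

# one score-resample draw: flip each non-missing cell with its per-cell
# probability to an ordinally adjacent value
.resample_values <- function(values, pcell) {
  u <- matrix(stats::runif(length(values)), nrow(values))
  d <- matrix(stats::runif(length(values)), nrow(values))
  flip <- !is.na(values) & u < pcell
  out <- values
  out[flip & values == 0L] <- 1L
  out[flip & values == 2L] <- 1L
  ones <- flip & values == 1L
  out[ones] <- ifelse(d[ones] < 0.5, 0L, 2L)
  out
}

.jitter_definitions <- function(definitions, range) {
  lapply(definitions, function(def) {
    step <- sample(seq(-range, range), length(def$weights), replace = TRUE)
    w <- def$weights + as.integer(step)
    w[w < 1L] <- 1L  # floor at 1; pmax() would drop the id names
    def$weights <- w
    def$max_raw <- 2L * sum(w)
    def
  })
}

#' Priority-set stability under perturbation
#'
#' Re-runs the scoring pipeline \code{n_draws} times under the scheme's
#' perturbation and records, per estuary and index, how often the estuary is
#' classified a priority, plus the mean Jaccard similarity between each
#' draw's priority set and the baseline (unperturbed) set. Only eligible
#' records enter; eligibility itself is never perturbed (missing values stay
#' missing).
#'
#' @param records A score table.
#' @param definitions Named list of index definitions.
#' @param rule An [eligibility_rule()].
#' @param scheme A [perturbation_scheme()].
#' @param criteria Criterion registry.
#' @return A list of class \code{stability_report}: \code{baseline} (logical
#'   estuary-by-index priority matrix), \code{priority_frequency} (numeric
#'   matrix in \eqn{[0,1]}), \code{jaccard_mean} (named per index),
#'   \code{always_priority} and \code{never_priority} (per-index name
#'   lists), \code{n_draws}, \code{scheme}.
#' @examples
#' tab <- generate_table(generator_config(n_estuaries = 8, seed = 2))
#' rep <- run_sensitivity(tab, scheme = perturbation_scheme(n_draws = 50))
#' rep$jaccard_mean
#' @export
run_sensitivity <- function(records,
                            definitions = default_index_definitions(),
                            rule = eligibility_rule(),
                            scheme = perturbation_scheme(),
                            criteria = default_criteria()) {
  stopifnot(inherits(scheme, "perturbation_scheme"))
  records <- score_table(records, criteria)
  if (is.null(names(definitions)) && length(definitions))
    names(definitions) <- vapply(definitions, `[[`, "", "name")
  eligible <- filter_eligible(records, rule, criteria)$eligible
  if (!nrow(eligible))
    stop("no eligible records to analyse", call. = FALSE)
  values <- .score_matrix(eligible, criteria)
  baseline <- .priority_flags(values, definitions)

  # per-cell flip probabilities from the certainty annotations
  cert <- .certainty_matrix(eligible, criteria)
  pcell <- matrix(scheme$flip_probabilities[["none"]], nrow(cert), ncol(cert),
                  dimnames = dimnames(cert))
  for (lev in c("1", "2", "3"))
    pcell[!is.na(cert) & cert == as.integer(lev)] <-
      scheme$flip_probabilities[[lev]]

  draws <- list()
  if (scheme$kind == "leave_one_criterion_out") {
    for (nm in names(definitions)) {
      def <- definitions[[nm]]
      for (drop_id in names(def$weights)) {
        d <- def
        d$weights <- def$weights[setdiff(names(def$weights), drop_id)]
        if (!length(d$weights)) next
        d$override <- intersect(d$override, names(d$weights))
        d$max_raw <- 2L * sum(d$weights)
        defs_i <- definitions
        defs_i[[nm]] <- d
        draws[[length(draws) + 1L]] <- .priority_flags(values, defs_i)
      }
    }
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    }, add = TRUE)
    set.seed(scheme$seed)
    for (i in seq_len(scheme$n_draws)) {
      if (scheme$kind == "score_resample") {
        draws[[i]] <- .priority_flags(.resample_values(values, pcell),
                                      definitions)
      } else {
        draws[[i]] <- .priority_flags(
          values, .jitter_definitions(definitions, scheme$weight_jitter_range)
        )
      }
    }
  }

  n <- length(draws)
  freq <- Reduce(`+`, draws, accumulate = FALSE) / n
  jac <- stats::setNames(numeric(length(definitions)), names(definitions))
  for (nm in names(definitions)) {
    base_set <- rownames(baseline)[baseline[, nm]]
    jac[nm] <- mean(vapply(draws, function(d) {
      compare_priority_sets(rownames(d)[d[, nm]], base_set)
    }, numeric(1L)))
  }
  structure(
    list(
      baseline = baseline,
      priority_frequency = freq,
      jaccard_mean = jac,
      always_priority = lapply(
        stats::setNames(colnames(freq), colnames(freq)),
        function(nm) rownames(freq)[freq[, nm] == 1]
      ),
      never_priority = lapply(
        stats::setNames(colnames(freq), colnames(freq)),
        function(nm) rownames(freq)[freq[, nm] == 0]
      ),
      n_draws = n,
      scheme = scheme
    ),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Priority-set stability (", x$scheme$kind, ", ", x$n_draws,
      " draw(s), seed ", x$scheme$seed, ")\n", sep = "")
  for (nm in names(x$jaccard_mean)) {
    cat(sprintf("  %-24s mean Jaccard vs baseline %.3f; always priority: %d, never: %d\n",
                nm, x$jaccard_mean[[nm]], length(x$always_priority[[nm]]),
                length(x$never_priority[[nm]])))
  }
  invisible(x)
}

#' Serialize a stability report to JSON
#'
#' @param report A [run_sensitivity()] result.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_stability_json <- function(report, path) {
  stopifnot(inherits(report, "stability_report"))
  json <- list(
    kind = report$scheme$kind,
    n_draws = report$n_draws,
    seed = report$scheme$seed,
    flip_probabilities = as.list(report$scheme$flip_probabilities),
    jaccard_mean = as.list(report$jaccard_mean),
    priority_frequency = lapply(
      stats::setNames(rownames(report$priority_frequency),
                      rownames(report$priority_frequency)),
      function(e) as.list(report$priority_frequency[e, ])
    ),
    always_priority = report$always_priority,
    never_priority = report$never_priority
  )
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
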