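#' The fourteen estuary evaluation criteria
#'
#' Returns the default registry of criteria used to evaluate estuaries for
#' conservation-aquaculture investment in Olympia oysters (\emph{Ostrea
#' lurida}). Criteria 1--4 are ecological (recruitment limitation, local
#' extinction risk, post-settlement mortality, population isolation); criteria
#' 5--14 capture social, regulatory and infrastructural feasibility. Each
#' criterion is phrased as a question and scored per estuary on an ordinal
#' 0/1/2 scale (0 = low, 1 = medium, 2 = high priority signal), with missing
#' knowledge recorded as \code{NA}.
#'
#' @return A data frame of class \code{oly_criteria} with one row per
#'   criterion and columns \code{id} (integer 1--14), \code{key} (short unique
#'   token used as a column name in score tables), \code{question} and
#'   \code{rationale}.
#' @examples
#' crit <- default_criteria()
#' crit[crit$key == "safe_to_eat", c("id", "question")]
#' @seealso [default_index_definitions()] for the weights attached to each
#'   criterion by the four indices.
#' @export
default_criteria <- function() {
  x <- data.frame(
    id = 1:14,
    key = c(
      "recruitment", "extinction_risk", "mortality", "isolation",
      "hatchery", "safe_to_eat", "harvest_regulations", "growth",
      "bivalves_farmed", "management_plan", "community_oyster_restoration",
      "community_bivalve_restoration", "tribes_first_nations",
      "community_grow_harvest"
    ),
    question = c(
      "Is larval recruitment limited in this estuary?",
      "Is the local Olympia oyster population at risk of extinction?",
      "Is post-settlement mortality low?",
      "How isolated is this Olympia oyster population from others?",
      "Has a nearby hatchery produced Olympia oyster spat from local broodstock under conservation protocols?",
      "Is it safe to eat shellfish grown here?",
      "Do regulations allow harvest of Olympia oysters?",
      "Is post-settlement growth of Olympia oysters high?",
      "Are Olympia oysters or other bivalves currently farmed in this estuary?",
      "Is Olympia oyster restoration part of an organization's management or conservation plan?",
      "Are community or volunteer groups engaged in Olympia oyster restoration?",
      "Are community groups engaged in restoration of other bivalve or shellfish species?",
      "Are Native American Tribes or First Nations engaged in bivalve restoration or wild harvest?",
      "Are non-commercial community groups growing shellfish for harvest?"
    ),
    rationale = c(
      "Aquaculture can make the largest difference where low recruitment chronically limits the population.",
      "Very small or declining adult populations facing local extinction stand to gain the most from enhancement.",
      "High post-settlement survival maximizes the return on outplanted juveniles; high-mortality sites waste investment.",
      "Isolated populations without larval subsidy from neighbours are more vulnerable and benefit more from aquaculture.",
      "A local conservation-protocol hatchery reduces translocation risks (pathogens, fouling species) and protects local genetic adaptation.",
      "Only waters safe for shellfish consumption can support community harvest or commercial production.",
      "Community harvest projects require that harvest of the species be legal.",
      "Fast growth shortens the time from outplant to harvest, which matters to harvesters and growers.",
      "Existing bivalve farming infrastructure and track record ease new or expanded Olympia oyster aquaculture.",
      "Permitting and investment are easier where restoration is already an institutional priority.",
      "Engaged local communities make aquaculture-based restoration more likely to succeed and to benefit people.",
      "Groups restoring similar species indicate capacity and interest transferable to Olympia oysters.",
      "Indigenous stewardship improves long-term restoration outcomes and sustains cultural harvest practices.",
      "Groups already growing and harvesting shellfish can steward and maintain restored oyster beds."
    ),
    stringsAsFactors = FALSE
  )
  class(x) <- c("oly_criteria", "data.frame")
  x
}

# id -> key lookup for a registry
.criterion_keys <- function(criteria = default_criteria()) {
  stats::setNames(criteria$key, as.character(criteria$id))
}

# resolve a vector of names that may be keys or ids into character ids
.resolve_criterion_ids <- function(x, criteria = default_criteria()) {
  x <- as.character(x)
  out <- character(length(x))
  for (i in seq_along(x)) {
    if (x[i] %in% as.character(criteria$id)) {
      out[i] <- x[i]
    } else if (x[i] %in% criteria$key) {
      out[i] <- as.character(criteria$id[criteria$key == x[i]])
    } else {
      stop("unknown criterion: '", x[i], "'", call. = FALSE)
    }
  }
  out
}

#' Define a weighted-sum index
#'
#' An index combines a subset of criteria through strictly positive integer
#' weights. The index value of an estuary is the weighted sum of its 0/1/2
#' criterion scores divided by the maximum possible sum (twice the total
#' weight), giving a score in \eqn{[0, 1]}. Criteria listed in
#' \code{override} are veto criteria: an effective score of 0 on any of them
#' (an explicit 0 or a missing value, which scores as 0) forces the whole
#' index to 0 regardless of the other criteria. An estuary is classified a
#' priority for the index when its score is \eqn{\ge} \code{threshold}; the
#' comparison is exact (integer cross-multiplication), so a score of exactly
#' 11/22 meets a threshold of 0.50.
#'
#' @param name Index name.
#' @param weights Named vector of strictly positive integer weights; names are
#'   criterion ids (\code{"1"}--\code{"14"}) or keys (e.g.
#'   \code{"recruitment"}). Criteria absent from \code{weights} do not enter
#'   the index.
#' @param override Criterion ids or keys (subset of the weighted criteria)
#'   whose zero score vetoes the index. Default none.
#' @param threshold Priority threshold in \eqn{(0, 1]}; a number or a string
#'   such as \code{"0.50"} or \code{"1/2"}, parsed to an exact rational.
#' @param criteria Criterion registry used to resolve keys.
#' @return An object of class \code{index_definition} with elements
#'   \code{name}, \code{weights} (named by criterion id), \code{override},
#'   \code{threshold} (exact rational) and \code{max_raw}.
#' @examples
#' index_definition("ecological_priority",
#'   c(recruitment = 4, extinction_risk = 3, mortality = 2, isolation = 2)
#' )
#' @export
index_definition <- function(name, weights, override = character(),
                             threshold = "0.50",
                             criteria = default_criteria()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("index 'name' must be a non-empty string", call. = FALSE)
  if (length(weights) == 0L || is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("'weights' must be a non-empty named vector", call. = FALSE)
  w <- as.numeric(weights)
  if (any(!is.finite(w)) || any(w <= 0) || any(w != round(w)))
    stop("all index weights must be strictly positive integers", call. = FALSE)
  ids <- .resolve_criterion_ids(names(weights), criteria)
  if (anyDuplicated(ids))
    stop("duplicate criterion in 'weights'", call. = FALSE)
  w <- stats::setNames(as.integer(w), ids)
  w <- w[order(as.integer(names(w)))]
  ov <- if (length(override)) .resolve_criterion_ids(override, criteria) else character()
  if (!all(ov %in% names(w)))
    stop("override criteria must be a subset of the weighted criteria", call. = FALSE)
  thr <- .as_rational(threshold)
  tv <- .rational_value(thr)
  if (tv <= 0 || tv > 1)
    stop("'threshold' must lie in (0, 1]", call. = FALSE)
  structure(
    list(
      name = name,
      weights = w,
      override = sort(unique(ov)),
      threshold = thr,
      max_raw = 2L * sum(w)
    ),
    class = "index_definition"
  )
}

#' @export
print.index_definition <- function(x, ...) {
  keys <- .criterion_keys()
  nm <- ifelse(names(x$weights) %in% names(keys),
               keys[names(x$weights)], names(x$weights))
  cat("Index definition: ", x$name, "\n", sep = "")
  cat("  weights:  ",
      paste0(nm, "=", x$weights, collapse = ", "), "\n", sep = "")
  if (length(x$override)) {
    ovnm <- ifelse(x$override %in% names(keys), keys[x$override], x$override)
    cat("  override: ", paste(ovnm, collapse = ", "),
        " (score 0 vetoes the index)\n", sep = "")
  }
  cat("  max raw:  ", x$max_raw, "\n", sep = "")
  cat("  priority threshold: ", format(x$threshold), "\n", sep = "")
  invisible(x)
}

#' The four default conservation-aquaculture indices
#'
#' Returns the standard index definitions: \emph{ecological priority} (where
#' would aquaculture most benefit the wild population), \emph{community
#' restoration}, \emph{community harvest} and \emph{commercial production}
#' (which project types are currently feasible where). Weights reflect
#' stakeholder consensus: recruitment limitation carries the highest
#' ecological weight (4), followed by extinction risk (3), then mortality and
#' isolation (2 each). The harvest-oriented indices carry veto criteria:
#' community harvest is vetoed by unsafe shellfish consumption or illegal
#' harvest, commercial production by unsafe consumption alone. All four use a
#' priority threshold of 0.50.
#'
#' @return Named list of [index_definition()] objects:
#'   \code{ecological_priority} (max raw score 22),
#'   \code{community_restoration} (18), \code{community_harvest} (24),
#'   \code{commercial_production} (18).
#' @examples
#' defs <- default_index_definitions()
#' defs$ecological_priority
#' sapply(defs, function(d) d$max_raw)
#' @export
default_index_definitions <- function() {
  list(
    ecological_priority = index_definition(
      "ecological_priority",
      c("1" = 4, "2" = 3, "3" = 2, "4" = 2)
    ),
    community_restoration = index_definition(
      "community_restoration",
      c("3" = 2, "5" = 1, "10" = 2, "11" = 2, "12" = 1, "13" = 1)
    ),
    community_harvest = index_definition(
      "community_harvest",
      c("3" = 2, "5" = 1, "6" = 3, "7" = 2, "8" = 1, "9" = 1, "13" = 1, "14" = 1),
      override = c("6", "7")
    ),
    commercial_production = index_definition(
      "commercial_production",
      c("3" = 1, "5" = 2, "6" = 3, "8" = 1, "9" = 1, "14" = 1),
      override = "6"
    )
  )
}
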