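# Independent brute-force oracle for the index algebra: explicit loops over
# criteria, plain integer arithmetic, no shared code with the package's
# vectorized implementation.

oracle_index <- function(values, weights, override_ids = character(),
                         thr_num = 1L, thr_den = 2L) {
  raw <- 0L
  for (id in names(weights)) {
    v <- values[[id]]
    if (is.null(v) || is.na(v)) v <- 0L
    raw <- raw + as.integer(weights[[id]]) * as.integer(v)
  }
  max_raw <- 0L
  for (id in names(weights)) max_raw <- max_raw + 2L * as.integer(weights[[id]])
  veto <- FALSE
  for (id in override_ids) {
    v <- values[[id]]
    if (is.null(v) || is.na(v)) v <- 0L
    if (v == 0L) veto <- TRUE
  }
  list(
    raw = raw,
    max_raw = max_raw,
    score = if (veto) 0 else raw / max_raw,
    override = veto,
    priority = if (veto) FALSE else (raw * thr_den >= max_raw * thr_num)
  )
}

# random score tables for property tests (independent of the package's
# generator so generator bugs cannot mask scoring bugs)
random_score_table <- function(n, seed, miss_rate = 0.15) {
  set.seed(seed)
  keys <- default_criteria()$key
  tab <- data.frame(
    estuary = sprintf("R-%04d", seq_len(n)),
    region = sample(c("BCC", "WA", "OR", "CA", "BCM"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  for (k in keys) {
    v <- sample(0:2, n, replace = TRUE)
    v[runif(n) < miss_rate] <- NA_integer_
    tab[[k]] <- v
    cert <- sample(1:3, n, replace = TRUE)
    cert[is.na(v)] <- NA_integer_
    tab[[paste0(k, "_certainty")]] <- cert
  }
  score_table(tab)
}

# named value list (by criterion id) for one row of a score table
record_value_list <- function(tab, i) {
  crit <- default_criteria()
  vals <- as.list(as.integer(tab[i, crit$key]))
  names(vals) <- as.character(crit$id)
  vals
}
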