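# Exact rational arithmetic for threshold classification.
#
# Index scores are ratios of small integers (raw weighted sum over maximum
# possible sum) and the priority rule is a >= comparison against a rational
# threshold. Boundary cases such as 11/22 vs 1/2 must classify
# deterministically, so thresholds are kept as integer numerator/denominator
# pairs and all comparisons are done by integer cross-multiplication, never
# by binary floating point.

.gcd <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

# num/den as a reduced integer pair with den > 0
.rational <- function(num, den) {
  num <- as.integer(num)
  den <- as.integer(den)
  if (is.na(num) || is.na(den) || den <= 0L)
    stop("invalid rational: denominator must be a positive integer", call. = FALSE)
  if (num != 0L) {
    g <- .gcd(abs(num), den)
    num <- num %/% g
    den <- den %/% g
  } else {
    den <- 1L
  }
  structure(c(num = num, den = den), class = "olyprior_rational")
}

# Parse a threshold given as a rational pair, a string ("0.50", "1/2") or a
# numeric. Numerics go through their decimal print representation so that
# 0.6 becomes exactly 3/5 rather than its binary approximation.
.as_rational <- function(x) {
  if (inherits(x, "olyprior_rational")) return(x)
  if (is.character(x)) {
    x <- trimws(x)
    if (grepl("/", x, fixed = TRUE)) {
      parts <- strsplit(x, "/", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) stop("cannot parse rational: ", x, call. = FALSE)
      return(.rational(as.integer(parts[1L]), as.integer(parts[2L])))
    }
    if (!grepl("^-?[0-9]*\\.?[0-9]+$", x))
      stop("cannot parse rational: ", x, call. = FALSE)
    if (grepl(".", x, fixed = TRUE)) {
      dec <- sub("^[^.]*\\.", "", x)
      den <- 10L^nchar(dec)
      num <- as.integer(round(as.numeric(x) * den))
      return(.rational(num, den))
    }
    return(.rational(as.integer(x), 1L))
  }
  if (is.numeric(x) && length(x) == 1L && is.finite(x)) {
    return(.as_rational(format(x, digits = 15L, scientific = FALSE)))
  }
  stop("cannot interpret as a rational number", call. = FALSE)
}

.rational_value <- function(r) unname(r["num"] / r["den"])

# a/b >= r ?  (b > 0)
.ge_rational <- function(a, b, r) {
  as.numeric(a) * as.numeric(r["den"]) >= as.numeric(b) * as.numeric(r["num"])
}

#' @export
format.olyprior_rational <- function(x, ...) {
  if (x["den"] == 1L) as.character(x["num"]) else paste0(x["num"], "/", x["den"])
}

#' @export
print.olyprior_rational <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
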