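#' Round half away from zero
#'
#' Reported registry percentages are rounded to whole percent with halves
#' going away from zero (so 23.5 -> 24), matching the usual presentation
#' of audit tables rather than R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Whole-percent share
#'
#' @param k Numerator count(s).
#' @param n Denominator count(s).
#' @return `100 * k / n` rounded half away from zero to whole percent;
#'   0 when `n` is 0.
#' @export
percent_of <- function(k, n) {
  len <- max(length(k), length(n))
  k <- rep_len(k, len); n <- rep_len(n, len)
  out <- numeric(len)
  out[n != 0] <- round_half_away(100 * k[n != 0] / n[n != 0])
  out
}

#' Count-weighted overall percentage
#'
#' Combines per-domain percentages into an overall figure weighted by the
#' per-domain trial counts, rounded to whole percent.
#'
#' @param percents Per-domain percentages.
#' @param counts Per-domain trial counts (weights).
#' @return A single whole-percent value.
#' @export
weighted_percent <- function(percents, counts) {
  stopifnot(length(percents) == length(counts), sum(counts) > 0)
  round_half_away(sum(percents * counts) / sum(counts))
}

# run code under a temporary RNG state; restores .Random.seed afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# apportion integer counts n*p_i by largest remainder so they sum to
# round(n * sum(p)); used for exact-count planting in the generator
apportion_counts <- function(n, probs) {
  raw <- n * probs
  base <- floor(raw)
  rem <- round(n * sum(probs)) - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
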