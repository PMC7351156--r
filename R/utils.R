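# Internal numeric and RNG helpers shared across modules.

#' Round half away from zero
#'
#' Display rounding used throughout the reports: exact halves round up
#' (2.65 -> 2.7), unlike base [round()]'s round-half-even. Computations are
#' carried at full precision; this is applied only when a value is reported.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.65, 1)  # 2.7, where round(2.65, 1) gives 2.6
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Integer percentages that sum to 100
#'
#' Largest-remainder apportionment of a count vector into integer
#' percentages summing to exactly 100. Ties in the fractional remainders go
#' to the category with the smaller count (then alphabetically), matching
#' the convention of the published composition tables.
#'
#' @param counts named non-negative integer vector.
#' @return named integer vector summing to 100.
#' @export
#' @examples
#' percent_int100(c(woody = 10, herb = 4, vine = 2))  # 62, 25, 13
percent_int100 <- function(counts) {
  if (is.null(names(counts)) || any(counts < 0) || sum(counts) == 0) {
    abort("`counts` must be a named non-negative vector with a positive sum.",
          class = "pvcrops_usage_error")
  }
  raw <- 100 * counts / sum(counts)
  out <- floor(raw)
  short <- 100 - sum(out)
  ord <- order(-(raw - out), counts, names(counts))
  take <- ord[seq_len(short)]
  out[take] <- out[take] + 1
  storage.mode(out) <- "integer"
  out
}

# Run `code` under a fixed seed, restoring the caller's RNG state after.
# All generator entry points route through this so no global state leaks.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Abort unless `x` is a single finite number.
check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "pvcrops_domain_error")
  }
  invisible(x)
}
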