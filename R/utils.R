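## Small internal helpers shared across the pipeline.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Derive a child seed from a master seed and integer keys
#'
#' Deterministic integer mixing kept below 2^31 so the result is a valid
#' `set.seed()` input. Different key tuples give different streams.
#' @noRd
derive_seed <- function(master, ...) {
  keys <- c(...)
  h <- as.double(master) %% 2147483629
  for (k in keys) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483629
  }
  as.integer(h)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Matches the conventional "half-up" rounding of printed accuracy tables
#' (base `round()` rounds half to even).
#' @noRd
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
stop_if_not_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", what), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
stop_if_not_count <- function(x, what, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be an integer >= %d", what, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
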