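# Shared numeric helpers.

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (2.345 -> 2.35 at two
#' decimals), the convention used by printed probability and summary tables,
#' in contrast to the IEEE round-half-even rule of [round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(c(2.345, 46.53465, 185.6818), c(2, 1, 0))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny guard so products such as 1.2 * 4.60, stored a hair below the tie,
  # still round as their decimal value would
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Truncated-normal draws by inverse-CDF; exact, no rejection loop.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Closed-form mean and SD of a normal truncated to [lower, upper].
tnorm_moments <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  ada <- if (is.finite(a)) a * da else 0
  bdb <- if (is.finite(b)) b * db else 0
  m <- mean + sd * (da - db) / Z
  v <- sd^2 * (1 + (ada - bdb) / Z - ((da - db) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

# Seed hygiene: set a local seed and restore the caller's RNG state on exit.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
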