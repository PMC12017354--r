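# Internal helpers: deterministic seed streams and calibrated truncated draws.

#' Evaluate code under a local RNG seed
#'
#' Saves and restores the global RNG state so that library code never
#' perturbs the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed < 2^31 from a master seed and arbitrary keys.
# Each subject/purpose pair gets its own reproducible stream so modules
# can be regenerated independently. Strings are absorbed one character
# at a time through a multiplicative LCG step so that structured id
# sets (P001, P002, ...) map to distinct streams.
derive_seed <- function(seed, ...) {
  x <- (as.double(seed) + 1) %% 2147483647
  for (k in list(...)) {
    codes <- if (is.character(k)) utf8ToInt(k) else as.double(k)
    for (cc in codes) {
      x <- (x * 48271 + cc + 1) %% 2147483647
    }
    x <- (x * 48271 + 7919) %% 2147483647
  }
  as.integer(x)
}

# Moments of a normal truncated below at `lower`.
truncnorm_moments <- function(mu, sd, lower) {
  a <- (lower - mu) / sd
  lam <- dnorm(a) / pnorm(a, lower.tail = FALSE)
  m <- mu + sd * lam
  v <- sd^2 * (1 + a * lam - lam^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

# Location mu* such that a N(mu*, sd) truncated below at `lower` has the
# requested mean. Printed group means are therefore recovered in
# expectation despite the hard floor (see vignette).
truncnorm_calibrate <- function(target_mean, sd, lower) {
  if (target_mean <= lower)
    stop("target mean must exceed the truncation bound")
  f <- function(mu) truncnorm_moments(mu, sd, lower)$mean - target_mean
  # truncated mean is increasing in mu and >= lower
  lo <- target_mean - 10 * sd
  hi <- target_mean + sd
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Draw from a lower-truncated normal whose post-truncation mean equals
# `target_mean` (rejection sampling; cheap at the tail depths used here).
rtrunc_meancal <- function(n, target_mean, sd, lower) {
  if (sd <= 0) return(rep(target_mean, n))
  mu <- truncnorm_calibrate(target_mean, sd, lower)
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 8, mu, sd)
    out <- c(out, x[x >= lower])
  }
  out[seq_len(n)]
}

# Round half up at `digits` decimals (display convention for reports).
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
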