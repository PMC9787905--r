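# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards so simulation helpers do not
#' disturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Truncated normal draw with bounded retries
#'
#' Redraws until the value exceeds `lower`; after `retries` failures raises a
#' simulation error (degenerate profiles should fail loudly, not loop).
#' @noRd
rnorm_pos <- function(n, mean, sd, lower = 0, retries = 100L) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  tries <- 0L
  while (length(bad) > 0L) {
    tries <- tries + 1L
    if (tries > retries)
      stop("simulation error: positivity resampling exhausted after ",
           retries, " retries (mean = ", signif(mean, 3), ", sd = ",
           signif(sd, 3), ")", call. = FALSE)
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable integer sub-seed derived from a master seed and a stream index
#' (kept well below 2^31).
#' @noRd
sub_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(index) %% 100003L
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
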