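# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded generators do not perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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

# Deterministically derive a child seed from a parent seed plus labels.
# Keeps results in [1, 2^31 - 2] so they are valid R integer seeds.
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(paste(p, collapse = "")))
    for (k in as.numeric(p)) h <- (h * 69069 + (k %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# moment-matched lognormal parameters for a given mean and sd (both > 0)
lnorm_params <- function(mean, sd) {
  stopifnot(all(mean > 0), all(sd > 0))
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}
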