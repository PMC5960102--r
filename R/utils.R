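## Internal helpers shared across modules.

#' @importFrom methods new validObject is slot setValidity show slotNames
#' @importFrom stats median pchisq phyper p.adjust aov TukeyHSD cor.test
#'   rgamma rbinom rpois runif setNames chisq.test aggregate
#' @importFrom utils read.delim write.table combn head tail
NULL

## Derive an integer sub-seed for a named generator stream from the master
## seed, so adding a generator never perturbs the draws of another.
streamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 1000003
  as.integer((abs(seed) + h * 2654435) %% .Machine$integer.max)
}

## Evaluate `expr` under a private RNG stream; the caller's RNG state is
## untouched.
withStream <- function(seed, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(streamSeed(seed, name))
  expr
}

## round() halves away from zero (base round() is banker's rounding); the
## rank-discrepancy scores need a sign-symmetric convention.
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
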