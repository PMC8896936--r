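# Seed plumbing.  Every stochastic stage draws from a stream derived from the
# one user-facing seed by hashing the stage name (and an optional index), so
# adding a stage never perturbs the draws of earlier stages.

.SEED_MOD <- 2147483647  # 2^31 - 1; derived seeds stay valid R integers

#' Derive a stage seed from a global seed
#'
#' Deterministically hashes a global integer seed together with a stage name
#' and an optional index into a new seed in `[1, 2^31 - 2]`.  Used so that
#' every pipeline stage (phantom generation, patch sampling, weight
#' initialisation, splits) consumes an independent, reproducible stream.
#'
#' @param seed global integer seed.
#' @param stage character stage name.
#' @param index optional non-negative integer (e.g. sample index).
#' @return an integer seed.
#' @examples
#' deriveSeed(42, "phantom", 3)
#' @export
deriveSeed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.numeric(seed) %% .SEED_MOD
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% .SEED_MOD
  h <- (h * 31 + as.numeric(index) %% .SEED_MOD) %% .SEED_MOD
  as.integer(h %% (.SEED_MOD - 2) + 1)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is restored afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
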