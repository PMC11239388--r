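# Internal helpers shared across modules.

# Two-sided normal p-value from an estimate and its SE.
norm_pval <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

# z quantile for a two-sided interval at `level`.
z_crit <- function(level) stats::qnorm((1 + level) / 2)

# Run `expr` under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
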