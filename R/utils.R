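# Internal helpers shared across modules.

# Derive a reproducible sub-seed for a named pipeline stage from one root
# seed, so that e.g. redrawing herbivory does not perturb the genotype draw.
# Kept below 2^31 - 1 so it is always a valid `set.seed()` input.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v)) %% 1000003L
  as.integer((abs(seed) %% 1000003L) * 2011L + h * 7919L) %% 2147483629L
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

# Centre and scale, mapping a constant vector to zeros instead of NaN.
# Used where a degenerate design (single family, single diversity level)
# must not poison a linear predictor. The user-facing `standardize()` in the
# statistics module is stricter and errors on constants.
safe_standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Symmetric Dirichlet(1) draw via gamma variates.
rdirichlet1 <- function(n) {
  g <- stats::rgamma(n, shape = 1)
  g / sum(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
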