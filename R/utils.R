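#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Every stochastic operation in the package
# takes an explicit seed and routes through here; nothing touches global RNG
# state permanently.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stream of child seeds from one parent seed, so independent stages
# (blocks, subjects) get reproducible but distinct substreams.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
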