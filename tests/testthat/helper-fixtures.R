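# Shared fixtures: built in code, deterministic under explicit seeds.

printed_ar_weights <- c(0.222, 0.104, 0.076)

with_seed_for_test <- withr::with_seed

# small experiment for cheap structural tests
small_config <- function(seed = 42) {
  synth_config(n_subjects = 4, n_blocks_per_subject = 4, n_trials = 60,
               seed = seed)
}

sample_skewness <- function(x) {
  ctr <- x - mean(x)
  mean(ctr^3) / mean(ctr^2)^1.5
}

# numeric integral of a density over [lo, hi]
integrate_density <- function(f, lo, hi) {
  stats::integrate(f, lo, hi, rel.tol = 1e-9, subdivisions = 500L)$value
}
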