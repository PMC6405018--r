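# Shared helpers: binomial acceptance bands and small fixtures.
# Bands are always derived from the binomial model at the replicate count
# actually used, never hard-coded.

band3se <- function(target, reps) 3 * sqrt(target * (1 - target) / reps)

expect_rate_equals <- function(est, target, reps) {
  expect_lte(abs(est - target), band3se(target, reps))
}

expect_rate_at_most <- function(est, alpha, reps) {
  expect_lte(est, alpha + band3se(alpha, reps))
}

# deterministic continuous fixture vectors
fix_x <- function(n, seed) withr::with_seed(seed, stats::rnorm(n))

# explicit small sign-flip set from +-1 rows
sign_set <- function(mat) {
  transformation_set(lapply(seq_len(nrow(mat)), function(i) sign_transform(mat[i, ])))
}
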