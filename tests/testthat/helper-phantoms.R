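# Shared fixtures, generated in code and memoised so expensive phantoms are
# built once per test run.

.phantom_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .phantom_cache)) {
    assign(key, builder(), envir = .phantom_cache)
  }
  get(key, envir = .phantom_cache)
}

# A small synthetic suite for property tests (full 20-nodule suite is built
# only in the end-to-end acceptance test).
small_suite <- function() {
  cached("small_suite", function() {
    synthesize_nodule_suite(n = 6, image_shape = c(160L, 160L),
                            cystic_fractions = seq(0.15, 0.85, length.out = 6),
                            seed = 42L)
  })
}

one_nodule <- function() small_suite()[[3]]

# Filled disk mask on a square frame.
disk_mask <- function(shape, center, radius) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((rows - center[1])^2 + (cols - center[2])^2 <= radius^2) * 1L
}

# Rank-based AUROC of a score separating two groups (Wilcoxon identity).
auroc <- function(score, is_positive) {
  r <- rank(score)
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
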