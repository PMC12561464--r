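# Shared fixtures, built in code.

# Boosted-prevalence configuration for unit tests: sub-percent treatment
# needs very large n for stable nuisance fits, so tests run at 5-10%
# prevalence; the realism target itself is covered by a dedicated large-n
# calibration test.
quick_config <- function(n = 4000, seed = 1, prevalence = 0.08, ...) {
  synthetic_config(n = n, seed = seed, treatment_prevalence = prevalence,
                   ...)
}

# Wrap bare gamma vectors as a reward matrix.
make_rewards <- function(gamma0, gamma1, T = NULL, y = NULL) {
  n <- length(gamma0)
  out <- data.frame(gamma0 = gamma0, gamma1 = gamma1,
                    pi_hat = rep(0.5, n), mu0 = gamma0, mu1 = gamma1,
                    T = if (is.null(T)) rep(0L, n) else T,
                    y = if (is.null(y)) rep(0L, n) else y)
  class(out) <- c("reward_matrix", "data.frame")
  out
}

# Independent AUC oracle: brute-force enumeration over all
# (positive, negative) pairs with the half-credit tie convention.
auc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Random small policy-tree instances for optimizer properties.
random_instance <- function(seed, n = 200, p = 3) {
  set.seed(seed)
  X <- as.data.frame(setNames(lapply(seq_len(p), function(i) rnorm(n)),
                              paste0("x", seq_len(p))))
  list(X = X, rewards = make_rewards(runif(n), runif(n)))
}
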