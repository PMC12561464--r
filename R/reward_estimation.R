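# Cross-fitted nuisance models and doubly-robust reward matrices.
#
# Propensity pi(x) = P(T = 1 | x) and outcome models mu_t(x) =
# P(death_24h = 1 | x, T = t) are random forests; every record's predictions
# come from forests not trained on it (stratified cross-fitting), the
# standard guard against own-fit overfitting leaking into the rewards. The
# doubly-robust reward
#   Gamma_i(t) = mu_t(x_i) + 1{T_i = t} (y_i - mu_t(x_i)) / pi_t(x_i)
# is consistent for the counterfactual mortality if either nuisance model is
# correct; lower is better (mortality scale).

#' Fit cross-fitted propensity and outcome forests
#'
#' @param X Model-matrix data.frame (numeric and factor covariates, no
#'   missing values).
#' @param T Binary treatment vector.
#' @param y Binary outcome vector (1 = death within 24 h).
#' @param n_folds Number of cross-fitting folds (default 5), stratified on
#'   the joint (T, y) classes.
#' @param eps Propensity clip bound in (0, 0.5); out-of-fold propensities
#'   are clipped to `[eps, 1 - eps]` before any inverse weighting. The
#'   default 0.05 caps any single record's inverse-propensity influence at
#'   20x: under rare treatment, looser clips let a handful of treated
#'   survivors dominate leaf-level mean rewards and the tree optimizer
#'   then chases that noise.
#' @param num_trees Trees per forest (default 200).
#' @param mtry Covariates tried per split. The default, half the covariate
#'   count, is deliberately larger than the classification rule-of-thumb
#'   (square root): with a couple dozen trauma-bay covariates of which a
#'   handful drive severity, small `mtry` over-smooths the outcome models
#'   toward the arm's marginal mortality, and the doubly-robust residual
#'   divides exactly that bias by the (small) propensity.
#' @param seed Integer seed; the fit is deterministic given it.
#' @return Object of class `nuisance_fit` with out-of-fold vectors `pi_hat`,
#'   `mu0`, `mu1`, the fold assignment, and the clip bound.
#' @export
fit_nuisance <- function(X, T, y, n_folds = 5L, eps = 0.05,
                         num_trees = 200L, mtry = NULL, seed = 1L) {
  n <- nrow(X)
  stopifnot(length(T) == n, length(y) == n)
  if (n_folds < 2 || n < n_folds) {
    stop("estimation error: need n >= n_folds >= 2", call. = FALSE)
  }
  if (length(unique(T)) < 2) {
    stop("estimation error: both treatment arms must be present",
         call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("estimation error: both outcome classes must be present",
         call. = FALSE)
  }
  if (eps <= 0 || eps >= 0.5) {
    stop("estimation error: eps must lie in (0, 0.5)", call. = FALSE)
  }
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 2))
  folds <- stratified_folds(interaction(T, y, drop = TRUE), n_folds, seed)
  if (any(tapply(T, folds, function(t) length(unique(t))) < 2)) {
    stop("estimation error: a fold lost a treatment arm despite stratification",
         call. = FALSE)
  }

  pi_hat <- mu0 <- mu1 <- numeric(n)
  for (f in seq_len(n_folds)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    pi_hat[test_idx] <- forest_prob(X[train_idx, , drop = FALSE], T[train_idx],
                                    X[test_idx, , drop = FALSE],
                                    num_trees, mtry, seed + f,
                                    balanced = TRUE)
    for (t in c(0L, 1L)) {
      arm <- train_idx[T[train_idx] == t]
      pred <- forest_prob(X[arm, , drop = FALSE], y[arm],
                          X[test_idx, , drop = FALSE],
                          num_trees, mtry, seed + 100L + f, balanced = FALSE)
      if (t == 0L) mu0[test_idx] <- pred else mu1[test_idx] <- pred
    }
  }
  pi_hat <- pmin(pmax(pi_hat, eps), 1 - eps)

  structure(list(pi_hat = pi_hat, mu0 = mu0, mu1 = mu1, folds = folds,
                 eps = eps, n = n, num_trees = as.integer(num_trees),
                 seed = as.integer(seed), fitted_on = NA_character_),
            class = "nuisance_fit")
}

# Probability-forest P(class = 1 | x); degenerates to a constant when the
# training labels are single-class (possible for the rare treated arm in a
# small fold complement).
forest_prob <- function(X_train, labels, X_test, num_trees, mtry, seed,
                        balanced) {
  labs <- factor(labels, levels = c(0, 1))
  if (length(unique(labels)) < 2) {
    return(rep(as.numeric(as.character(labs[1])), nrow(X_test)))
  }
  cw <- if (balanced) {
    tab <- table(labs)
    as.numeric(length(labs) / (2 * tab))
  } else {
    NULL
  }
  dat <- data.frame(X_train, .label = labs, check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = dat, probability = TRUE,
    num.trees = num_trees, min.node.size = 10, class.weights = cw,
    mtry = min(mtry, ncol(X_train)),
    respect.unordered.factors = "order", seed = seed, num.threads = 1
  )
  as.numeric(predict(fit, data = X_test, num.threads = 1)$predictions[, "1"])
}

stratified_folds <- function(strata, n_folds, seed) {
  set.seed(as.integer(seed))
  folds <- integer(length(strata))
  for (s in levels(strata)) {
    idx <- which(strata == s)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

#' Assemble a nuisance object from given predictions
#'
#' Useful for hand-constructed examples and for robustness checks that
#' deliberately misspecify one nuisance component while keeping the other
#' correct.
#'
#' @param pi_hat,mu0,mu1 Prediction vectors (propensity, untreated-arm and
#'   treated-arm outcome probabilities).
#' @param eps Propensity clip bound (applied to `pi_hat`).
#' @return A `nuisance_fit`.
#' @export
nuisance_manual <- function(pi_hat, mu0, mu1, eps = 0.05) {
  n <- length(pi_hat)
  stopifnot(length(mu0) == n, length(mu1) == n)
  structure(list(pi_hat = pmin(pmax(pi_hat, eps), 1 - eps), mu0 = mu0,
                 mu1 = mu1, folds = rep(NA_integer_, n), eps = eps, n = n,
                 num_trees = NA_integer_, seed = NA_integer_,
                 fitted_on = "manual"),
            class = "nuisance_fit")
}

#' Doubly-robust reward matrix
#'
#' For each record, the estimated 24-h mortality probability under each
#' action: the outcome-model prediction, corrected by the inverse-propensity
#' weighted residual on the arm actually received. The arm not received gets
#' the plug-in prediction exactly.
#'
#' @param models A `nuisance_fit`.
#' @param T,y Observed treatment and outcome vectors.
#' @return Data.frame of class `reward_matrix` with columns `gamma0`,
#'   `gamma1`, `pi_hat`, `mu0`, `mu1`, `T`, `y`.
#' @export
doubly_robust_rewards <- function(models, T, y) {
  stopifnot(inherits(models, "nuisance_fit"))
  n <- models$n
  if (length(T) != n || length(y) != n) {
    stop("alignment error: T/y do not match the nuisance fit", call. = FALSE)
  }
  pi1 <- models$pi_hat
  pi0 <- 1 - pi1
  gamma1 <- models$mu1 + (T == 1) * (y - models$mu1) / pi1
  gamma0 <- models$mu0 + (T == 0) * (y - models$mu0) / pi0
  out <- data.frame(gamma0 = gamma0, gamma1 = gamma1, pi_hat = pi1,
                    mu0 = models$mu0, mu1 = models$mu1, T = T, y = y)
  class(out) <- c("reward_matrix", "data.frame")
  out
}

#' Out-of-fold discrimination of the nuisance models
#'
#' ROC AUCs of the propensity model against observed treatment and of each
#' outcome model against observed mortality within its own arm.
#'
#' @param models A `nuisance_fit`.
#' @param T,y Observed treatment and outcome vectors.
#' @return Named numeric vector: `propensity`, `outcome_t0`, `outcome_t1`.
#' @export
nuisance_auc <- function(models, T, y) {
  stopifnot(inherits(models, "nuisance_fit"))
  c(propensity = auc_safe(T, models$pi_hat),
    outcome_t0 = auc_safe(y[T == 0], models$mu0[T == 0]),
    outcome_t1 = auc_safe(y[T == 1], models$mu1[T == 1]))
}

auc_safe <- function(labels, scores) {
  if (length(unique(labels)) < 2) {
    stop("undefined-AUC error: labels contain a single class", call. = FALSE)
  }
  as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(0, 1),
                                 direction = "<", quiet = TRUE)))
}
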