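hand_tree <- function(feature, threshold, action_left, action_right,
                      missing_side = "right") {
  leaf <- function(id, action) list(type = "leaf", id = id, action = action,
                                    n = 0L, mean0 = NA_real_,
                                    mean1 = NA_real_, strength = 0)
  node <- list(type = "split", feature = feature, kind = "numeric",
               threshold = threshold, categories = NULL,
               missing_side = missing_side,
               left = leaf(1L, action_left), right = leaf(2L, action_right))
  structure(list(node = node, features = feature,
                 hp = tree_hyperparameters(max_depth = 1), n_train = 0L,
                 n_splits = 1L, n_leaves = 2L, J = NA_real_),
            class = "policy_tree")
}

test_that("a policy identical to observed assignments has zero ARR everywhere", {
  X <- data.frame(x = c(-1, -2, 1, 2))
  rw <- make_rewards(gamma0 = c(0.3, 0.4, 0.5, 0.6),
                     gamma1 = c(0.2, 0.1, 0.9, 0.8),
                     T = c(1L, 1L, 0L, 0L))
  tree <- hand_tree("x", 0, action_left = 1L, action_right = 0L)
  rep <- evaluate_policy(tree, rw, X, original = "dr")
  expect_equal(rep$overall$arr, 0)
  expect_equal(rep$groups$arr, c(0, 0))
  expect_equal(rep$leaves$arr, c(0, 0))
})

test_that("the observed-original convention uses the empirical outcome", {
  X <- data.frame(x = c(-1, -2, 1, 2))
  rw <- make_rewards(gamma0 = c(0.3, 0.4, 0.5, 0.6),
                     gamma1 = c(0.2, 0.1, 0.9, 0.8),
                     T = c(1L, 1L, 0L, 0L), y = c(1L, 0L, 0L, 1L))
  tree <- hand_tree("x", 0, action_left = 1L, action_right = 0L)
  rep <- evaluate_policy(tree, rw, X)
  expect_equal(rep$original_risk, "observed")
  expect_equal(rep$overall$original, mean(c(1, 0, 0, 1)))
  g1 <- rep$groups[rep$groups$group == "observed REBOA", ]
  expect_equal(g1$original, 0.5)   # the group's observed mortality rate
})

test_that("a four-record report matches hand arithmetic", {
  # records: (T, g0, g1): 1:(1,.5,.9) 2:(0,.2,.1) 3:(0,.4,.8) 4:(1,.7,.3)
  # tree: x < 0 -> action 1, else 0; x = (-1, -1, 1, 1)
  # original  = (.9, .2, .4, .3), mean .45
  # actions   = (1, 1, 0, 0); prescribed = (.9, .1, .4, .7), mean .525
  X <- data.frame(x = c(-1, -1, 1, 1))
  rw <- make_rewards(gamma0 = c(0.5, 0.2, 0.4, 0.7),
                     gamma1 = c(0.9, 0.1, 0.8, 0.3),
                     T = c(1L, 0L, 0L, 1L))
  tree <- hand_tree("x", 0, action_left = 1L, action_right = 0L)
  rep <- evaluate_policy(tree, rw, X, original = "dr")
  expect_equal(rep$overall$original, 0.45)
  expect_equal(rep$overall$prescribed, 0.525)
  expect_equal(rep$overall$arr, -0.075)
  expect_equal(rep$overall$arr_pct, -7.5)
  # observed-treated group: records 1 and 4: original (.9+.3)/2, prescribed (.9+.7)/2
  g1 <- rep$groups[rep$groups$group == "observed REBOA", ]
  expect_equal(g1$original, 0.6)
  expect_equal(g1$prescribed, 0.8)
  # leaves: leaf 1 = records 1,2; leaf 2 = records 3,4
  expect_equal(rep$leaves$original, c(0.55, 0.35))
  expect_equal(rep$leaves$prescribed, c(0.5, 0.55))
  expect_equal(rep$leaves$n, c(2L, 2L))
})

test_that("n-weighted leaf aggregates reconstruct the overall row exactly", {
  inst <- random_instance(31, n = 400, p = 3)
  rw <- inst$rewards
  rw$T <- rbinom(400, 1, 0.3)
  tree <- grow_policy_tree(rw, inst$X,
                           tree_hyperparameters(max_depth = 2,
                                                min_samples_leaf = 20))
  rep <- evaluate_policy(tree, rw, inst$X)
  lv <- rep$leaves
  expect_equal(sum(lv$n * lv$original) / sum(lv$n), rep$overall$original,
               tolerance = 1e-12)
  expect_equal(sum(lv$n * lv$prescribed) / sum(lv$n),
               rep$overall$prescribed, tolerance = 1e-12)
  expect_equal(sum(lv$n * lv$arr) / sum(lv$n), rep$overall$arr,
               tolerance = 1e-12)
  expect_equal(sum(lv$n), rep$overall$n)
})

test_that("leaf-table formatting computes ARR before rounding", {
  # unrounded ARR 0.07984 prints as ARR 0.080 but ARR% 7.984: the percent
  # column comes from the unrounded difference, not from the printed 3-dp
  # probabilities (whose subtraction would give 7.980)
  tab <- format_leaf_table(data.frame(leaf = c(5, 13),
                                      original = c(0.95940, 0.8884),
                                      prescribed = c(0.87956, 0.88835)))
  expect_equal(tab$arr, c("0.080", "0.000"))
  expect_equal(tab$arr_pct, c("7.984", "0.005"))

  zero <- format_leaf_table(data.frame(leaf = 1, original = 0.5,
                                       prescribed = 0.5))
  expect_equal(zero$arr, "0.000")
  expect_equal(zero$arr_pct, "0.000")
})

test_that("the training half is refused by the test-reward leakage guard", {
  sim <- generate_cohort(quick_config(n = 1200, seed = 41))
  feats <- derive_features(apply_study_filters(sim$cohort)$cohort)
  halves <- split_cohort(feats, seed = 1)
  expect_error(estimate_test_rewards(halves$train), "leakage guard")
})

test_that("test-side rewards are a pure function of the test half", {
  sim <- generate_cohort(quick_config(n = 1600, seed = 43, prevalence = 0.15))
  feats <- derive_features(apply_study_filters(sim$cohort)$cohort)
  halves <- split_cohort(feats, seed = 5)
  a <- estimate_test_rewards(halves$test, n_folds = 3, num_trees = 50,
                             seed = 9)
  # mutate a copy of the training half; test rewards must be unaffected
  halves$train$death_24h <- sample(halves$train$death_24h)
  b <- estimate_test_rewards(halves$test, n_folds = 3, num_trees = 50,
                             seed = 9)
  expect_identical(a$rewards, b$rewards)
})

test_that("the stratified split halves the cohort within (T, y) cells", {
  sim <- generate_cohort(quick_config(n = 3000, seed = 47, prevalence = 0.1))
  feats <- derive_features(apply_study_filters(sim$cohort)$cohort)
  halves <- split_cohort(feats, seed = 3)
  expect_equal(nrow(halves$train) + nrow(halves$test), nrow(feats))
  expect_length(intersect(halves$train$id, halves$test$id), 0)
  for (t in 0:1) {
    for (y in 0:1) {
      n_tr <- sum(halves$train$reboa == t & halves$train$death_24h == y)
      n_te <- sum(halves$test$reboa == t & halves$test$death_24h == y)
      expect_lte(abs(n_tr - n_te), 1)
    }
  }
})

test_that("test-half DR rewards recover true potential outcomes under randomization", {
  cfg <- synthetic_config(n = 6000, seed = 51, treatment_prevalence = 0.5,
                          confounding_coeffs = c(),
                          filter_noise = c())
  sim <- generate_cohort(cfg)
  feats <- derive_features(sim$cohort)
  attr(feats, "role") <- "test"
  est <- estimate_test_rewards(feats, n_folds = 3, num_trees = 100,
                               seed = 13)
  for (t in 0:1) {
    gam <- if (t == 1) est$rewards$gamma1 else est$rewards$gamma0
    truth_mean <- mean(if (t == 1) sim$truth$p1 else sim$truth$p0)
    mc_se <- sd(gam) / sqrt(length(gam))
    expect_lt(abs(mean(gam) - truth_mean), 3 * mc_se)
  }
})
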