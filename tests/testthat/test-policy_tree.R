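test_that("candidate splits are quantile midpoints, memberships, or empty", {
  X <- data.frame(v = c(1, 2, 3), const = c(5, 5, 5),
                  bin = c(0, 1, 0), grp = c("a", "b", "c"))
  expect_equal(candidate_splits(X, "v", 32), c(1.5, 2.5))
  expect_equal(candidate_splits(X, "const", 32), numeric(0))
  expect_equal(candidate_splits(X, "bin", 32), 0.5)
  expect_equal(candidate_splits(X, "grp", 32), list("a", "b", "c"))
  expect_error(candidate_splits(X, "nope"), "unknown feature")
})

test_that("a globally dominant action yields a depth-0 tree", {
  set.seed(1)
  n <- 300
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  rw <- make_rewards(gamma0 = runif(n, 0.5, 1), gamma1 = runif(n, 0, 0.4))
  tree <- grow_policy_tree(rw, X, tree_hyperparameters(max_depth = 3,
                                                       min_samples_leaf = 10))
  expect_equal(tree$n_splits, 0)
  expect_true(all(prescribe(tree, X)$action == 1))
})

test_that("an overwhelming complexity penalty forces a root-only tree", {
  set.seed(2)
  n <- 400
  X <- data.frame(x1 = rnorm(n))
  rw <- make_rewards(gamma0 = ifelse(X$x1 < 0, 0, 1),
                     gamma1 = ifelse(X$x1 < 0, 1, 0))
  hp <- tree_hyperparameters(max_depth = 3, min_samples_leaf = 10, cp = 1e6)
  tree <- grow_policy_tree(rw, X, hp)
  expect_equal(tree$n_splits, 0)
  # the single leaf carries the globally better action (ties to 0)
  expect_equal(tree$node$action,
               as.integer(sum(rw$gamma1) < sum(rw$gamma0)))
})

test_that("a planted threshold rule is recovered within one grid step", {
  set.seed(3)
  n <- 500
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  rw <- make_rewards(gamma0 = ifelse(X$x1 < 0, 0.8, 0.2) + rnorm(n, 0, 0.02),
                     gamma1 = ifelse(X$x1 < 0, 0.2, 0.8) + rnorm(n, 0, 0.02))
  hp <- tree_hyperparameters(max_depth = 1, min_samples_leaf = 20,
                             n_thresholds = 32)
  tree <- grow_policy_tree(rw, X, hp)
  expect_equal(tree$node$feature, "x1")
  grid <- candidate_splits(X, "x1", 32)
  step <- max(diff(sort(grid)))
  expect_lt(abs(tree$node$threshold), step + 1e-9)
  # and it matches the exhaustive oracle on the same candidate grid
  bf <- brute_force_optimal_tree(rw, X, max_depth = 1, n_thresholds = 8,
                                 min_samples_leaf = 20)
  g8 <- grow_policy_tree(rw, X, tree_hyperparameters(
    max_depth = 1, min_samples_leaf = 20, n_thresholds = 8))
  expect_equal(g8$J, bf$J, tolerance = 1e-12)
})

test_that("depth-1 enumeration matches a fully hand-computed instance", {
  # x = 1..4; gamma0 = (0,0,1,1), gamma1 = (1,1,0,0).
  # Candidates are midpoints {1.5, 2.5, 3.5}. Splitting at 2.5 gives
  # left {1,2} -> action 0 (cost 0), right {3,4} -> action 1 (cost 0),
  # J = 0; every other split or leaf leaves cost >= 1.
  X <- data.frame(x = c(1, 2, 3, 4))
  rw <- make_rewards(gamma0 = c(0, 0, 1, 1), gamma1 = c(1, 1, 0, 0))
  bf <- brute_force_optimal_tree(rw, X, max_depth = 1, n_thresholds = 8,
                                 min_samples_leaf = 1)
  expect_equal(bf$J, 0)
  expect_equal(bf$node$threshold, 2.5)
  expect_equal(bf$node$left$action, 0L)
  expect_equal(bf$node$right$action, 1L)
})

test_that("the brute-force oracle refuses oversized instances", {
  inst <- random_instance(1, n = 501)
  expect_error(brute_force_optimal_tree(inst$rewards, inst$X),
               "size guard")
})

test_that("local search never increases the objective", {
  for (s in 1:20) {
    inst <- random_instance(s, n = 150, p = 2)
    hp <- tree_hyperparameters(max_depth = 2, min_samples_leaf = 5,
                               n_thresholds = 8,
                               local_search_passes = 3)
    tree <- grow_policy_tree(inst$rewards, inst$X, hp)
    refined <- local_search(tree, inst$rewards, inst$X, hp)
    expect_lte(refined$J, tree$J + 1e-12)
    # and the oracle never does worse than either
    bf <- brute_force_optimal_tree(inst$rewards, inst$X, max_depth = 2,
                                   n_thresholds = 8, min_samples_leaf = 5)
    expect_lte(bf$J, refined$J + 1e-12)
  }
})

test_that("local search leaves fixed points unchanged", {
  X <- data.frame(x = c(1, 2, 3, 4))
  rw <- make_rewards(gamma0 = c(0, 0, 1, 1), gamma1 = c(1, 1, 0, 0))
  hp <- tree_hyperparameters(max_depth = 1, min_samples_leaf = 1,
                             n_thresholds = 8, local_search_passes = 5)
  tree <- grow_policy_tree(rw, X, hp)
  refined <- local_search(tree, rw, X, hp)
  expect_equal(refined$J, tree$J)
  expect_equal(refined$node$threshold, tree$node$threshold)

  # single-leaf tree: nothing to search
  leaf_tree <- grow_policy_tree(make_rewards(rep(1, 10), rep(0, 10)),
                                data.frame(x = rnorm(10)),
                                tree_hyperparameters(max_depth = 0))
  expect_equal(local_search(leaf_tree, make_rewards(rep(1, 10), rep(0, 10)),
                            data.frame(x = rnorm(10)))$J, leaf_tree$J)
})

test_that("prescriptions are invariant to monotone feature transforms", {
  set.seed(4)
  n <- 300
  X <- data.frame(x1 = rnorm(n), x2 = runif(n))
  rw <- make_rewards(gamma0 = ifelse(X$x1 < 0.3, 0.7, 0.2) + rnorm(n, 0, 0.05),
                     gamma1 = ifelse(X$x2 > 0.6, 0.1, 0.6) + rnorm(n, 0, 0.05))
  hp <- tree_hyperparameters(max_depth = 2, min_samples_leaf = 15,
                             n_thresholds = 16)
  t1 <- grow_policy_tree(rw, X, hp)
  X2 <- data.frame(x1 = exp(X$x1), x2 = X$x2^3)
  t2 <- grow_policy_tree(rw, X2, hp)
  expect_equal(prescribe(t1, X)$action, prescribe(t2, X2)$action)
})

test_that("routing handles hand-built trees and missing split values", {
  leaf <- function(id, action) list(type = "leaf", id = id, action = action,
                                    n = 0L, mean0 = NA_real_,
                                    mean1 = NA_real_, strength = 0)
  node <- list(type = "split", feature = "gcs", kind = "numeric",
               threshold = 5, categories = NULL, missing_side = "right",
               left = leaf(1L, 1L), right = leaf(2L, 0L))
  tree <- structure(list(node = node, features = "gcs",
                         hp = tree_hyperparameters(max_depth = 1),
                         n_train = 0L, n_splits = 1L, n_leaves = 2L,
                         J = NA_real_), class = "policy_tree")
  # GCS below 5 is prescribed REBOA; missing GCS routes to the right leaf
  out <- prescribe(tree, data.frame(gcs = c(3, 14, NA)))
  expect_equal(out$action, c(1L, 0L, 0L))
  expect_equal(out$leaf, c(1L, 2L, 2L))
  expect_error(prescribe(tree, data.frame(age = 1)), "gcs")

  # depth-0 tree prescribes its single action everywhere
  rw <- make_rewards(rep(0.2, 20), rep(0.7, 20))
  t0 <- grow_policy_tree(rw, data.frame(x = rnorm(20)),
                         tree_hyperparameters(max_depth = 0))
  expect_true(all(prescribe(t0, data.frame(x = c(-99, 0, NA)))$action == 0))
})

test_that("grid search honours scoring and simplicity tie-breaks", {
  set.seed(5)
  n <- 600
  X <- data.frame(x1 = rnorm(n))
  flat <- make_rewards(gamma0 = rep(0.5, n), gamma1 = rep(0.2, n))
  grid <- list(tree_hyperparameters(max_depth = 2, min_samples_leaf = 20),
               tree_hyperparameters(max_depth = 0, min_samples_leaf = 20))
  res <- grid_search_hyperparams(flat, X, grid, n_folds = 3, seed = 2)
  expect_equal(res$best$max_depth, 0L)  # tie broken to the simpler tree
  expect_equal(nrow(res$cv), 2)

  single <- grid_search_hyperparams(flat, X, grid[1], n_folds = 3, seed = 2)
  expect_equal(single$best$max_depth, 2L)
  expect_error(grid_search_hyperparams(flat, X, list()), "empty")

  # a real planted subgroup makes depth 2 beat depth 0
  rw <- make_rewards(
    gamma0 = ifelse(X$x1 < -0.5, 0.9, 0.1) + rnorm(n, 0, 0.02),
    gamma1 = ifelse(X$x1 < -0.5, 0.1, 0.9) + rnorm(n, 0, 0.02))
  res2 <- grid_search_hyperparams(rw, X, grid, n_folds = 3, seed = 2)
  expect_equal(res2$best$max_depth, 2L)
})

test_that("trees are reproducible and serialize losslessly", {
  inst <- random_instance(7, n = 250, p = 3)
  hp <- tree_hyperparameters(max_depth = 2, min_samples_leaf = 10,
                             n_thresholds = 16)
  t1 <- grow_policy_tree(inst$rewards, inst$X, hp)
  t2 <- grow_policy_tree(inst$rewards, inst$X, hp)
  expect_identical(policy_tree_json(t1), policy_tree_json(t2))

  back <- policy_tree_from_json(policy_tree_json(t1))
  expect_equal(prescribe(back, inst$X)$action, prescribe(t1, inst$X)$action)
  expect_equal(back$J, t1$J)

  dot <- policy_tree_dot(t1)
  expect_match(dot, "digraph policy_tree")
  expect_match(dot, "Prescribe")
})
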