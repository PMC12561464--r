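# Binary policy trees minimizing mean doubly-robust mortality reward.
#
# Objective (to minimize):
#   J(tree) = (1/n) * sum_i Gamma_i(a(leaf(x_i))) + cp * (#splits)
# Each leaf prescribes the action with the lower mean reward among its
# training rows (ties to action 0, No REBOA). Growth is greedy recursive
# partitioning over quantile-derived candidate thresholds computed once per
# feature from the full training data; a local-search refinement collapses
# subtrees and re-optimizes internal splits. An exhaustive enumerator over
# the same candidate grid serves as the optimality oracle on small
# instances. Every numeric split carries an explicit side for missing
# values, chosen during search by the objective, so informative missingness
# (e.g. an unobtainable blood pressure) is a first-class split.

#' Policy-tree hyperparameters
#'
#' @param max_depth Maximum tree depth (0 = a single prescribing leaf).
#' @param min_samples_leaf Minimum training rows per leaf.
#' @param cp Complexity penalty per split, on the mean-reward scale.
#' @param n_thresholds Number of empirical quantiles per numeric feature
#'   from which candidate thresholds (midpoints) are derived.
#' @param local_search_passes Maximum local-search sweeps after greedy
#'   growth.
#' @param seed Integer seed (growth is deterministic; recorded for
#'   provenance).
#' @return Validated list of class `tree_hyperparameters`.
#' @export
tree_hyperparameters <- function(max_depth = 3L, min_samples_leaf = 50L,
                                 cp = 0, n_thresholds = 32L,
                                 local_search_passes = 2L, seed = 1L) {
  hp <- list(max_depth = as.integer(max_depth),
             min_samples_leaf = as.integer(min_samples_leaf), cp = cp,
             n_thresholds = as.integer(n_thresholds),
             local_search_passes = as.integer(local_search_passes),
             seed = as.integer(seed))
  if (hp$max_depth < 0) stop("max_depth must be >= 0", call. = FALSE)
  if (hp$min_samples_leaf < 1) stop("min_samples_leaf must be >= 1",
                                    call. = FALSE)
  if (!is.numeric(hp$cp) || hp$cp < 0) stop("cp must be >= 0", call. = FALSE)
  if (hp$n_thresholds < 1) stop("n_thresholds must be >= 1", call. = FALSE)
  if (hp$local_search_passes < 0) stop("local_search_passes must be >= 0",
                                       call. = FALSE)
  class(hp) <- "tree_hyperparameters"
  hp
}

#' Candidate splits for one feature
#'
#' Numeric features yield thresholds at the midpoints between consecutive
#' distinct empirical quantiles (type-1, so quantiles are observed values)
#' of the non-missing data; categorical features yield one-level-versus-rest
#' membership subsets. Constant features yield nothing.
#'
#' @param X Data.frame of covariates.
#' @param feature Column name.
#' @param n_thresholds Quantile count for numeric features.
#' @return Numeric vector of thresholds, or a list of character level
#'   subsets for categorical features.
#' @export
candidate_splits <- function(X, feature, n_thresholds = 32L) {
  if (!feature %in% names(X)) {
    stop(sprintf("schema error: unknown feature '%s'", feature),
         call. = FALSE)
  }
  x <- X[[feature]]
  if (is.factor(x) || is.character(x) || is.logical(x)) {
    lv <- sort(unique(as.character(x[!is.na(x)])))
    if (length(lv) < 2) return(list())
    if (length(lv) == 2) return(list(lv[1]))
    return(lapply(lv, identity))
  }
  obs <- x[!is.na(x)]
  u <- sort(unique(obs))
  if (length(u) < 2) return(numeric(0))
  qs <- unique(as.numeric(quantile(obs, probs = seq(0, 1, length.out =
                                                      max(2, n_thresholds)),
                                   type = 1, names = FALSE)))
  # Each threshold sits between a selected quantile (an observed value,
  # type-1) and the next distinct observed value, so the induced partition
  # depends only on ranks and survives monotone transforms.
  qs <- sort(qs[qs < u[length(u)]])
  succ <- u[findInterval(qs, u) + 1]
  (qs + succ) / 2
}

feature_candidates <- function(X, n_thresholds) {
  res <- lapply(names(X), function(f) {
    x <- X[[f]]
    kind <- if (is.factor(x) || is.character(x) || is.logical(x)) {
      "categorical"
    } else {
      "numeric"
    }
    list(kind = kind, cand = candidate_splits(X, f, n_thresholds))
  })
  names(res) <- names(X)
  res
}

split_goes_left <- function(node, xcol) {
  if (node$kind == "numeric") {
    gl <- xcol < node$threshold
  } else {
    gl <- as.character(xcol) %in% node$categories
  }
  gl[is.na(xcol)] <- node$missing_side == "left"
  gl
}

# ---- greedy growth -------------------------------------------------------

#' Grow a policy tree by greedy recursive partitioning
#'
#' A split is accepted only if it strictly lowers the penalized objective
#' and both children retain `min_samples_leaf` training rows; each leaf then
#' prescribes the action with the lower mean reward (ties to No REBOA).
#'
#' @param rewards A `reward_matrix` (columns `gamma0`, `gamma1`).
#' @param X Covariate data.frame aligned with `rewards`.
#' @param hp A [tree_hyperparameters()].
#' @return Object of class `policy_tree`.
#' @export
grow_policy_tree <- function(rewards, X, hp = tree_hyperparameters()) {
  n <- nrow(X)
  if (n == 0) stop("empty input", call. = FALSE)
  if (nrow(rewards) != n) {
    stop("alignment error: rewards and X differ in length", call. = FALSE)
  }
  cands <- feature_candidates(X, hp$n_thresholds)
  node <- grow_subtree(seq_len(n), 0L, rewards$gamma0, rewards$gamma1, X,
                       cands, hp, n)
  finalize_tree(node, rewards, X, hp)
}

grow_subtree <- function(idx, depth, g0, g1, X, cands, hp, n) {
  s0 <- sum(g0[idx])
  s1 <- sum(g1[idx])
  leaf_cost <- min(s0, s1)
  if (depth >= hp$max_depth || length(idx) < 2 * hp$min_samples_leaf) {
    return(list(type = "leaf"))
  }
  bs <- best_split_minpair(idx, X, cands, g0, g1, hp$min_samples_leaf)
  if (is.null(bs) || !(bs$cost + hp$cp * n < leaf_cost)) {
    return(list(type = "leaf"))
  }
  gl <- split_goes_left(bs, X[[bs$feature]][idx])
  list(type = "split", feature = bs$feature, kind = bs$kind,
       threshold = bs$threshold, categories = bs$categories,
       missing_side = bs$missing_side,
       left = grow_subtree(idx[gl], depth + 1L, g0, g1, X, cands, hp, n),
       right = grow_subtree(idx[!gl], depth + 1L, g0, g1, X, cands, hp, n))
}

# Flat list of every candidate split (feature x threshold/subset x missing
# side); shared by the brute-force oracle and the restart phase of local
# search.
enumerate_all_splits <- function(X, cands) {
  splits <- list()
  for (f in names(cands)) {
    info <- cands[[f]]
    has_na <- anyNA(X[[f]])
    sides <- if (has_na) c("left", "right") else "right"
    if (info$kind == "numeric") {
      for (t in info$cand) {
        for (side in sides) {
          splits[[length(splits) + 1L]] <-
            list(feature = f, kind = "numeric", threshold = t,
                 categories = NULL, missing_side = side)
        }
      }
    } else {
      for (subset in info$cand) {
        for (side in sides) {
          splits[[length(splits) + 1L]] <-
            list(feature = f, kind = "categorical", threshold = NULL,
                 categories = subset, missing_side = side)
        }
      }
    }
  }
  splits
}

# Best single split when both children become optimal-action leaves:
# minimize min(sum g0_L, sum g1_L) + min(sum g0_R, sum g1_R).
best_split_minpair <- function(idx, X, cands, g0, g1, msl) {
  best <- NULL
  for (f in names(cands)) {
    info <- cands[[f]]
    if (info$kind == "numeric") {
      if (!length(info$cand)) next
      cand <- eval_numeric_minpair(X[[f]][idx], g0[idx], g1[idx], info$cand,
                                   msl)
      if (!is.null(cand) && (is.null(best) || cand$cost < best$cost)) {
        best <- c(cand, list(feature = f, kind = "numeric",
                             categories = NULL))
      }
    } else {
      if (!length(info$cand)) next
      xv <- as.character(X[[f]][idx])
      g0v <- g0[idx]
      g1v <- g1[idx]
      has_na <- anyNA(xv)
      sides <- if (has_na) c("left", "right") else "right"
      for (subset in info$cand) {
        member <- !is.na(xv) & xv %in% subset
        for (side in sides) {
          gl <- member | (is.na(xv) & side == "left")
          nl <- sum(gl)
          if (nl < msl || length(xv) - nl < msl) next
          cost <- min(sum(g0v[gl]), sum(g1v[gl])) +
            min(sum(g0v[!gl]), sum(g1v[!gl]))
          if (is.null(best) || cost < best$cost) {
            best <- list(cost = cost, threshold = NULL, missing_side = side,
                         feature = f, kind = "categorical",
                         categories = subset)
          }
        }
      }
    }
  }
  best
}

eval_numeric_minpair <- function(xv, g0v, g1v, thr, msl) {
  obs <- !is.na(xv)
  nm <- sum(!obs)
  m0 <- sum(g0v[!obs])
  m1 <- sum(g1v[!obs])
  xo <- xv[obs]
  if (!length(xo)) return(NULL)
  o <- order(xo)
  xs <- xo[o]
  c0 <- c(0, cumsum(g0v[obs][o]))
  c1 <- c(0, cumsum(g1v[obs][o]))
  nobs <- length(xs)
  tot0 <- c0[nobs + 1]
  tot1 <- c1[nobs + 1]
  nl <- findInterval(thr, xs)
  best <- NULL
  sides <- if (nm > 0) c("left", "right") else "right"
  for (side in sides) {
    ml0 <- if (side == "left") m0 else 0
    ml1 <- if (side == "left") m1 else 0
    nL <- nl + if (side == "left") nm else 0L
    nR <- (nobs - nl) + if (side == "right") nm else 0L
    s0l <- c0[nl + 1] + ml0
    s1l <- c1[nl + 1] + ml1
    s0r <- (tot0 + m0) - s0l
    s1r <- (tot1 + m1) - s1l
    cost <- pmin(s0l, s1l) + pmin(s0r, s1r)
    ok <- nL >= msl & nR >= msl
    if (!any(ok)) next
    cost[!ok] <- Inf
    j <- which.min(cost)
    if (is.null(best) || cost[j] < best$cost) {
      best <- list(cost = cost[j], threshold = thr[j], missing_side = side)
    }
  }
  best
}

# ---- routing, statistics, finalization -----------------------------------

route_rows <- function(node, X, idx, leaf_counter = NULL) {
  action <- integer(length(idx))
  leaf <- integer(length(idx))
  walk <- function(nd, pos) {
    if (nd$type == "leaf") {
      action[pos] <<- nd$action
      leaf[pos] <<- nd$id
      return(invisible())
    }
    gl <- split_goes_left(nd, X[[nd$feature]][idx[pos]])
    if (any(gl)) walk(nd$left, pos[gl])
    if (any(!gl)) walk(nd$right, pos[!gl])
  }
  if (length(idx)) walk(node, seq_along(idx))
  list(action = action, leaf = leaf)
}

count_splits <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + count_splits(node$left) + count_splits(node$right)
}

# Recompute leaf statistics and actions from the training routing, number
# leaves in preorder, and package the tree with its objective value.
finalize_tree <- function(node, rewards, X, hp) {
  g0 <- rewards$gamma0
  g1 <- rewards$gamma1
  n <- nrow(X)
  next_id <- 0L
  assign_stats <- function(nd, idx) {
    if (nd$type == "leaf") {
      next_id <<- next_id + 1L
      s0 <- sum(g0[idx])
      s1 <- sum(g1[idx])
      m <- length(idx)
      action <- if (m > 0 && s1 < s0) 1L else 0L
      mean0 <- if (m) s0 / m else NA_real_
      mean1 <- if (m) s1 / m else NA_real_
      return(list(type = "leaf", id = next_id, action = action, n = m,
                  mean0 = mean0, mean1 = mean1,
                  strength = if (m) max(mean0, mean1) - min(mean0, mean1)
                             else 0))
    }
    gl <- split_goes_left(nd, X[[nd$feature]][idx])
    nd$left <- assign_stats(nd$left, idx[gl])
    nd$right <- assign_stats(nd$right, idx[!gl])
    nd
  }
  node <- assign_stats(node, seq_len(n))
  routed <- route_rows(node, X, seq_len(n))
  nspl <- count_splits(node)
  J <- sum(ifelse(routed$action == 1, g1, g0)) / n + hp$cp * nspl
  structure(list(node = node, features = names(X), hp = hp, n_train = n,
                 n_splits = nspl, n_leaves = next_id, J = J),
            class = "policy_tree")
}

tree_split_features <- function(node) {
  if (node$type == "leaf") return(character(0))
  unique(c(node$feature, tree_split_features(node$left),
           tree_split_features(node$right)))
}

#' Prescribe actions with a policy tree
#'
#' Routes each row to a terminal leaf (missing split values follow the
#' split's configured missing side) and returns that leaf's prescribed
#' action and id.
#'
#' @param tree A `policy_tree`.
#' @param X Covariate data.frame containing the tree's split features.
#' @return List with integer vectors `action` (0/1) and `leaf` (leaf id).
#' @export
prescribe <- function(tree, X) {
  stopifnot(inherits(tree, "policy_tree"))
  need <- tree_split_features(tree$node)
  absent <- setdiff(need, names(X))
  if (length(absent)) {
    stop(sprintf("schema error: X lacks split feature(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  route_rows(tree$node, X, seq_len(nrow(X)))
}

#' Mean prescribed reward of a tree on a reward matrix
#'
#' @param tree A `policy_tree`.
#' @param rewards A `reward_matrix` aligned with `X`.
#' @param X Covariate data.frame.
#' @param cp_penalty Include the tree's `cp * #splits` penalty (default
#'   `TRUE`, giving the training objective J).
#' @return The (penalized) mean prescribed reward.
#' @export
tree_objective <- function(tree, rewards, X, cp_penalty = TRUE) {
  a <- prescribe(tree, X)$action
  val <- mean(ifelse(a == 1, rewards$gamma1, rewards$gamma0))
  if (cp_penalty) val <- val + tree$hp$cp * tree$n_splits
  val
}

# ---- local search --------------------------------------------------------

#' Local-search refinement of a policy tree
#'
#' Repeated sweeps over internal nodes trying (a) collapsing the subtree to
#' its best single leaf and (b) re-optimizing the node's split while holding
#' both child subtrees fixed; only strict objective improvements that keep
#' every leaf at `min_samples_leaf` are accepted, so the output objective
#' never exceeds the input objective.
#'
#' @param tree A `policy_tree`.
#' @param rewards,X Training rewards and covariates.
#' @param hp Hyperparameters (defaults to the tree's own).
#' @return A refined `policy_tree` with `J` no larger than the input's.
#' @export
local_search <- function(tree, rewards, X, hp = tree$hp) {
  stopifnot(inherits(tree, "policy_tree"))
  n <- nrow(X)
  g0 <- rewards$gamma0
  g1 <- rewards$gamma1
  cands <- feature_candidates(X, hp$n_thresholds)
  node <- tree$node
  improved_any <- FALSE

  stat_leaf <- function(idx) {
    s0 <- sum(g0[idx])
    s1 <- sum(g1[idx])
    m <- length(idx)
    list(type = "leaf", id = 0L, action = if (m > 0 && s1 < s0) 1L else 0L,
         n = m, mean0 = if (m) s0 / m else NA_real_,
         mean1 = if (m) s1 / m else NA_real_,
         strength = if (m) abs(s0 - s1) / m else 0)
  }

  sweep_node <- function(nd, idx, depth) {
    improved <- FALSE
    if (nd$type == "leaf") {
      # (c) re-split a leaf when depth budget remains: after an upstream
      # split changed, a leaf's rows may now support a profitable split
      if (depth < hp$max_depth && length(idx) >= 2 * hp$min_samples_leaf) {
        bs <- best_split_minpair(idx, X, cands, g0, g1,
                                 hp$min_samples_leaf)
        leaf_cost <- min(sum(g0[idx]), sum(g1[idx]))
        if (!is.null(bs) && bs$cost + hp$cp * n < leaf_cost) {
          gl_new <- split_goes_left(bs, X[[bs$feature]][idx])
          nd <- list(type = "split", feature = bs$feature, kind = bs$kind,
                     threshold = bs$threshold, categories = bs$categories,
                     missing_side = bs$missing_side,
                     left = stat_leaf(idx[gl_new]),
                     right = stat_leaf(idx[!gl_new]))
          improved <- TRUE
        } else {
          return(list(node = nd, improved = FALSE))
        }
      } else {
        return(list(node = nd, improved = FALSE))
      }
    }

    # (a) collapse to the best leaf
    routed <- route_rows(nd, X, idx)
    sub_cost <- sum(ifelse(routed$action == 1, g1[idx], g0[idx])) +
      hp$cp * n * count_splits(nd)
    leaf_cost <- min(sum(g0[idx]), sum(g1[idx]))
    if (length(idx) >= hp$min_samples_leaf && leaf_cost < sub_cost) {
      return(list(node = stat_leaf(idx), improved = TRUE))
    }

    # (b) re-optimize this node's split with child subtrees held fixed
    aL <- route_rows(nd$left, X, idx)$action
    aR <- route_rows(nd$right, X, idx)$action
    vL <- ifelse(aL == 1, g1[idx], g0[idx])
    vR <- ifelse(aR == 1, g1[idx], g0[idx])
    gl_now <- split_goes_left(nd, X[[nd$feature]][idx])
    cost_now <- sum(vL[gl_now]) + sum(vR[!gl_now])
    bs <- best_split_fixed(idx, X, cands, vL, vR, hp$min_samples_leaf)
    if (!is.null(bs) && bs$cost < cost_now) {
      cand_nd <- nd
      cand_nd$feature <- bs$feature
      cand_nd$kind <- bs$kind
      cand_nd$threshold <- bs$threshold
      cand_nd$categories <- bs$categories
      cand_nd$missing_side <- bs$missing_side
      if (leaves_feasible(cand_nd, X, idx, hp$min_samples_leaf)) {
        nd <- cand_nd
        improved <- TRUE
      }
    }

    gl <- split_goes_left(nd, X[[nd$feature]][idx])
    resL <- sweep_node(nd$left, idx[gl], depth + 1L)
    resR <- sweep_node(nd$right, idx[!gl], depth + 1L)
    nd$left <- resL$node
    nd$right <- resR$node
    list(node = nd, improved = improved || resL$improved || resR$improved)
  }

  run_passes <- function(start_node) {
    nd <- finalize_tree(start_node, rewards, X, hp)$node
    for (p in seq_len(max(0L, hp$local_search_passes))) {
      res <- sweep_node(nd, seq_len(n), 0L)
      # refresh leaf actions/statistics so the next pass costs moves
      # against up-to-date routing
      nd <- finalize_tree(res$node, rewards, X, hp)$node
      if (!res$improved) break
    }
    finalize_tree(nd, rewards, X, hp)
  }

  best <- run_passes(node)

  # Restart phase: greedy growth is myopic at the root, so re-grow the tree
  # from alternative root splits and keep the best objective. All roots are
  # tried when the instance fits a fixed work budget (on small instances
  # with depth <= 2 this makes the search exhaustive, since greedy depth-1
  # children already scan every split); otherwise only the top-scoring
  # roots by single-split objective are tried.
  if (hp$local_search_passes > 0 && hp$max_depth >= 1) {
    roots <- enumerate_all_splits(X, cands)
    if (length(roots) * n > 2e5 && length(roots) > 8) {
      score <- vapply(roots, function(sp) {
        gl <- split_goes_left(sp, X[[sp$feature]])
        nl <- sum(gl)
        if (nl < hp$min_samples_leaf || n - nl < hp$min_samples_leaf) {
          return(Inf)
        }
        min(sum(g0[gl]), sum(g1[gl])) + min(sum(g0[!gl]), sum(g1[!gl]))
      }, numeric(1))
      roots <- roots[order(score)[seq_len(8)]]
    }
    all_idx <- seq_len(n)
    for (sp in roots) {
      gl <- split_goes_left(sp, X[[sp$feature]])
      nl <- sum(gl)
      if (nl < hp$min_samples_leaf || n - nl < hp$min_samples_leaf) next
      cand_node <- c(sp, list(
        type = "split",
        left = grow_subtree(all_idx[gl], 1L, g0, g1, X, cands, hp, n),
        right = grow_subtree(all_idx[!gl], 1L, g0, g1, X, cands, hp, n)))
      cand_tree <- run_passes(cand_node)
      if (cand_tree$J < best$J - 1e-12) best <- cand_tree
    }
  }

  # Guard: never return a tree worse than the input.
  if (best$J > tree$J + 1e-12) tree else best
}

leaves_feasible <- function(node, X, idx, msl) {
  ok <- TRUE
  walk <- function(nd, pos) {
    if (!ok) return(invisible())
    if (nd$type == "leaf") {
      if (length(pos) < msl) ok <<- FALSE
      return(invisible())
    }
    gl <- split_goes_left(nd, X[[nd$feature]][idx[pos]])
    walk(nd$left, pos[gl])
    walk(nd$right, pos[!gl])
  }
  walk(node, seq_along(idx))
  ok
}

# Best partition minimizing sum_left vL + sum_right vR (fixed per-row arm
# values), over the same candidate grid as growth.
best_split_fixed <- function(idx, X, cands, vL, vR, msl) {
  best <- NULL
  for (f in names(cands)) {
    info <- cands[[f]]
    if (!length(info$cand)) next
    xv <- X[[f]][idx]
    if (info$kind == "numeric") {
      cand <- eval_numeric_fixed(xv, vL, vR, info$cand, msl)
      if (!is.null(cand) && (is.null(best) || cand$cost < best$cost)) {
        best <- c(cand, list(feature = f, kind = "numeric",
                             categories = NULL))
      }
    } else {
      xc <- as.character(xv)
      has_na <- anyNA(xc)
      sides <- if (has_na) c("left", "right") else "right"
      for (subset in info$cand) {
        member <- !is.na(xc) & xc %in% subset
        for (side in sides) {
          gl <- member | (is.na(xc) & side == "left")
          nl <- sum(gl)
          if (nl < msl || length(xc) - nl < msl) next
          cost <- sum(vL[gl]) + sum(vR[!gl])
          if (is.null(best) || cost < best$cost) {
            best <- list(cost = cost, threshold = NULL, missing_side = side,
                         feature = f, kind = "categorical",
                         categories = subset)
          }
        }
      }
    }
  }
  best
}

eval_numeric_fixed <- function(xv, vL, vR, thr, msl) {
  obs <- !is.na(xv)
  nm <- sum(!obs)
  mL <- sum(vL[!obs])
  mR <- sum(vR[!obs])
  xo <- xv[obs]
  if (!length(xo)) return(NULL)
  o <- order(xo)
  xs <- xo[o]
  A <- c(0, cumsum(vL[obs][o]))
  B <- c(0, cumsum(vR[obs][o]))
  nobs <- length(xs)
  nl <- findInterval(thr, xs)
  best <- NULL
  sides <- if (nm > 0) c("left", "right") else "right"
  for (side in sides) {
    nL <- nl + if (side == "left") nm else 0L
    nR <- (nobs - nl) + if (side == "right") nm else 0L
    cost <- A[nl + 1] + (B[nobs + 1] - B[nl + 1]) +
      if (side == "left") mL else mR
    ok <- nL >= msl & nR >= msl
    if (!any(ok)) next
    cost[!ok] <- Inf
    j <- which.min(cost)
    if (is.null(best) || cost[j] < best$cost) {
      best <- list(cost = cost[j], threshold = thr[j], missing_side = side)
    }
  }
  best
}

# ---- exhaustive small-instance oracle ------------------------------------

#' Exhaustively optimal tree on a small instance
#'
#' Enumerates every tree up to the requested depth over the quantile
#' candidate grid (all features, thresholds, and missing sides) and returns
#' a J-minimizing tree. Guarded to small instances; used as the optimality
#' oracle for the greedy + local-search optimizer.
#'
#' @param rewards,X Rewards and covariates (n <= 500, <= 4 features).
#' @param max_depth 0, 1, or 2.
#' @param n_thresholds Candidate quantiles per numeric feature (<= 8).
#' @param min_samples_leaf Minimum rows per leaf.
#' @param cp Complexity penalty per split.
#' @return A `policy_tree` minimizing J over the enumerated space.
#' @export
brute_force_optimal_tree <- function(rewards, X, max_depth = 2L,
                                     n_thresholds = 8L,
                                     min_samples_leaf = 1L, cp = 0) {
  n <- nrow(X)
  if (n > 500 || ncol(X) > 4 || n_thresholds > 8 || max_depth > 2) {
    stop("size guard error: brute force limited to n <= 500, <= 4 features, <= 8 thresholds, depth <= 2",
         call. = FALSE)
  }
  g0 <- rewards$gamma0
  g1 <- rewards$gamma1
  cands <- feature_candidates(X, n_thresholds)
  splits <- enumerate_all_splits(X, cands)
  cost0 <- function(idx) min(sum(g0[idx]), sum(g1[idx]))
  penalty <- cp * n

  best_sub1 <- function(idx, depth_allowed) {
    best <- list(cost = cost0(idx), node = list(type = "leaf"))
    if (depth_allowed < 1) return(best)
    for (sp in splits) {
      gl <- split_goes_left(sp, X[[sp$feature]][idx])
      nl <- sum(gl)
      if (nl < min_samples_leaf || length(idx) - nl < min_samples_leaf) next
      cost <- cost0(idx[gl]) + cost0(idx[!gl]) + penalty
      if (cost < best$cost) {
        best <- list(cost = cost,
                     node = c(sp, list(type = "split",
                                       left = list(type = "leaf"),
                                       right = list(type = "leaf"))))
      }
    }
    best
  }

  all_idx <- seq_len(n)
  best <- best_sub1(all_idx, min(1L, max_depth))
  if (max_depth >= 2) {
    for (sp in splits) {
      gl <- split_goes_left(sp, X[[sp$feature]][all_idx])
      nl <- sum(gl)
      if (nl < min_samples_leaf || n - nl < min_samples_leaf) next
      subL <- best_sub1(all_idx[gl], 1L)
      subR <- best_sub1(all_idx[!gl], 1L)
      cost <- subL$cost + subR$cost + penalty
      if (cost < best$cost) {
        best <- list(cost = cost,
                     node = c(sp, list(type = "split", left = subL$node,
                                       right = subR$node)))
      }
    }
  }
  hp <- tree_hyperparameters(max_depth = max_depth,
                             min_samples_leaf = min_samples_leaf, cp = cp,
                             n_thresholds = n_thresholds,
                             local_search_passes = 0L)
  finalize_tree(best$node, rewards, X, hp)
}

# ---- hyperparameter grid search ------------------------------------------

#' Grid search over tree hyperparameters by cross-validated prescribed reward
#'
#' Each hyperparameter setting is scored by the k-fold cross-validated mean
#' prescribed reward on the training rewards (folds stratified on observed
#' treatment). Ties prefer simpler trees: smaller `max_depth`, then larger
#' `cp`, then larger `min_samples_leaf`.
#'
#' @param rewards,X Training rewards and covariates.
#' @param grid Non-empty list of [tree_hyperparameters()].
#' @param n_folds Cross-validation folds (default 3).
#' @param seed Fold-assignment seed.
#' @return List with `best` (the winning hyperparameters) and `cv`
#'   (data.frame of per-setting scores).
#' @export
grid_search_hyperparams <- function(rewards, X, grid, n_folds = 3L,
                                    seed = 1L) {
  if (!length(grid)) stop("configuration error: empty hyperparameter grid",
                          call. = FALSE)
  folds <- stratified_folds(factor(rewards$T), n_folds, seed)
  g0 <- rewards$gamma0
  g1 <- rewards$gamma1
  cv <- vapply(grid, function(hp) {
    vals <- vapply(seq_len(n_folds), function(f) {
      tr <- which(folds != f)
      te <- which(folds == f)
      rw <- rewards[tr, , drop = FALSE]
      tree <- grow_policy_tree(rw, X[tr, , drop = FALSE], hp)
      tree <- local_search(tree, rw, X[tr, , drop = FALSE], hp)
      a <- prescribe(tree, X[te, , drop = FALSE])$action
      mean(ifelse(a == 1, g1[te], g0[te]))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  tab <- data.frame(
    max_depth = vapply(grid, `[[`, integer(1), "max_depth"),
    min_samples_leaf = vapply(grid, `[[`, integer(1), "min_samples_leaf"),
    cp = vapply(grid, `[[`, numeric(1), "cp"),
    n_thresholds = vapply(grid, `[[`, integer(1), "n_thresholds"),
    local_search_passes = vapply(grid, `[[`, integer(1),
                                 "local_search_passes"),
    cv_reward = cv
  )
  o <- order(signif(cv, 12), tab$max_depth, -tab$cp,
             -tab$min_samples_leaf)
  list(best = grid[[o[1]]], cv = tab)
}

# ---- serialization and rendering -----------------------------------------

node_to_list <- function(node) {
  if (node$type == "leaf") {
    return(list(type = "leaf", id = node$id, action = node$action,
                n = node$n, mean_gamma0 = node$mean0,
                mean_gamma1 = node$mean1, strength = node$strength))
  }
  list(type = "split", feature = node$feature, kind = node$kind,
       threshold = node$threshold, categories = as.list(node$categories),
       missing_side = node$missing_side, left = node_to_list(node$left),
       right = node_to_list(node$right))
}

list_to_node <- function(lst) {
  if (lst$type == "leaf") {
    return(list(type = "leaf", id = as.integer(lst$id),
                action = as.integer(lst$action), n = as.integer(lst$n),
                mean0 = as.numeric(lst$mean_gamma0),
                mean1 = as.numeric(lst$mean_gamma1),
                strength = as.numeric(lst$strength)))
  }
  list(type = "split", feature = lst$feature, kind = lst$kind,
       threshold = if (is.null(lst$threshold)) NULL else
         as.numeric(lst$threshold),
       categories = if (length(lst$categories)) unlist(lst$categories) else
         NULL,
       missing_side = lst$missing_side, left = list_to_node(lst$left),
       right = list_to_node(lst$right))
}

#' Serialize a policy tree to canonical JSON
#' @param tree A `policy_tree`.
#' @return A JSON string.
#' @export
policy_tree_json <- function(tree) {
  stopifnot(inherits(tree, "policy_tree"))
  as.character(jsonlite::toJSON(list(
    hyperparameters = unclass(tree$hp), n_train = tree$n_train,
    n_splits = tree$n_splits, n_leaves = tree$n_leaves, J = tree$J,
    node = node_to_list(tree$node)
  ), auto_unbox = TRUE, digits = NA, null = "null"))
}

#' Deserialize a policy tree from JSON
#' @param json JSON string or path to a JSON file.
#' @return A `policy_tree`.
#' @export
policy_tree_from_json <- function(json) {
  lst <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  hp <- do.call(tree_hyperparameters, lst$hyperparameters)
  structure(list(node = list_to_node(lst$node), features = NULL, hp = hp,
                 n_train = as.integer(lst$n_train),
                 n_splits = as.integer(lst$n_splits),
                 n_leaves = as.integer(lst$n_leaves),
                 J = as.numeric(lst$J)),
            class = "policy_tree")
}

split_label <- function(node) {
  if (node$kind == "numeric") {
    sprintf("%s < %g (NA: %s)", node$feature, node$threshold,
            node$missing_side)
  } else {
    sprintf("%s in {%s} (NA: %s)", node$feature,
            paste(node$categories, collapse = ","), node$missing_side)
  }
}

leaf_label <- function(node) {
  sprintf("Prescribe %s | n=%d, mean(G0)=%.3f, mean(G1)=%.3f, strength=%.3f",
          if (node$action == 1) "REBOA" else "No REBOA", node$n,
          node$mean0, node$mean1, node$strength)
}

#' Export a policy tree as a Graphviz DOT description
#'
#' Terminal leaves are shaded blue (REBOA) or red (No REBOA) with intensity
#' proportional to prescription strength: darker means a more confident
#' prescription.
#'
#' @param tree A `policy_tree`.
#' @return A character scalar of DOT source.
#' @export
policy_tree_dot <- function(tree) {
  stopifnot(inherits(tree, "policy_tree"))
  strengths <- c()
  collect <- function(nd) {
    if (nd$type == "leaf") strengths <<- c(strengths, nd$strength)
    else { collect(nd$left); collect(nd$right) }
  }
  collect(tree$node)
  smax <- max(strengths, 1e-12)
  lines <- c("digraph policy_tree {",
             "  node [shape=box, style=filled, fontname=Helvetica];")
  counter <- 0L
  emit <- function(nd) {
    counter <<- counter + 1L
    me <- sprintf("n%d", counter)
    if (nd$type == "leaf") {
      frac <- 0.15 + 0.85 * nd$strength / smax
      base <- if (nd$action == 1) c(70, 110, 230) else c(220, 60, 50)
      rgb_mix <- round(255 - frac * (255 - base))
      lines <<- c(lines, sprintf(
        "  %s [label=\"Leaf %d\\nPrescribe %s\\nN = %d\", fillcolor=\"#%02X%02X%02X\"];",
        me, nd$id, if (nd$action == 1) "REBOA" else "No REBOA", nd$n,
        rgb_mix[1], rgb_mix[2], rgb_mix[3]))
    } else {
      lines <<- c(lines, sprintf(
        "  %s [label=\"%s\", fillcolor=\"#F2F2F2\"];", me,
        gsub("\"", "'", split_label(nd))))
      l <- emit(nd$left)
      r <- emit(nd$right)
      lines <<- c(lines,
                  sprintf("  %s -> %s [label=\"yes\"];", me, l),
                  sprintf("  %s -> %s [label=\"no\"];", me, r))
    }
    me
  }
  emit(tree$node)
  paste(c(lines, "}"), collapse = "\n")
}

#' @export
print.policy_tree <- function(x, ...) {
  cat(sprintf(
    "Policy tree: %d leaves, %d splits, depth <= %d, n_train = %d, J = %.6f\n",
    x$n_leaves, x$n_splits, x$hp$max_depth, x$n_train, x$J))
  rec <- function(nd, indent, prefix) {
    pad <- strrep("  ", indent)
    if (nd$type == "leaf") {
      cat(sprintf("%s%s[%d] %s\n", pad, prefix, nd$id, leaf_label(nd)))
    } else {
      cat(sprintf("%s%s%s\n", pad, prefix, split_label(nd)))
      rec(nd$left, indent + 1, "yes: ")
      rec(nd$right, indent + 1, "no:  ")
    }
  }
  rec(x$node, 0, "")
  invisible(x)
}
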