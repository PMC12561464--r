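# Descriptive group-comparison tables and the end-to-end pipeline driver.

#' Compare two groups with descriptive statistics
#'
#' Categorical variables are reported as n (%) per group and compared with
#' Pearson's chi-squared test (no continuity correction by default);
#' continuous variables as median (IQR, linear-interpolation quartiles) and
#' compared with the Kruskal-Wallis test. Missing values are excluded
#' pairwise; p-values below 0.001 display as "<0.001".
#'
#' @param data Data.frame.
#' @param group Name of a binary grouping column.
#' @param variables Character vector of variable names to compare.
#' @param kinds Named character vector mapping each variable to
#'   `"categorical"` or `"continuous"`.
#' @param correct Apply Yates continuity correction for 2x2 tables
#'   (default `FALSE`).
#' @return Data.frame with one row per variable (or per level for
#'   categoricals): formatted per-group summaries, the test statistic, the
#'   numeric p-value and its display form.
#' @export
compare_groups <- function(data, group, variables, kinds, correct = FALSE) {
  g <- data[[group]]
  if (length(unique(g[!is.na(g)])) != 2) {
    stop("grouping column must take exactly two values", call. = FALSE)
  }
  lv <- sort(unique(g[!is.na(g)]))
  rows <- list()
  for (v in variables) {
    x <- data[[v]]
    ok <- !is.na(x) & !is.na(g)
    if (kinds[[v]] == "categorical") {
      tab <- table(factor(x[ok]), factor(g[ok], levels = lv))
      test <- suppressWarnings(chisq.test(tab, correct = correct))
      for (l in rownames(tab)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = l,
          group0 = sprintf("%d (%.1f%%)", tab[l, 1],
                           100 * tab[l, 1] / sum(tab[, 1])),
          group1 = sprintf("%d (%.1f%%)", tab[l, 2],
                           100 * tab[l, 2] / sum(tab[, 2])),
          statistic = as.numeric(test$statistic), p_value = test$p.value,
          p_display = format_p(test$p.value), stringsAsFactors = FALSE)
      }
    } else {
      test <- kruskal.test(x[ok], factor(g[ok], levels = lv))
      fmt <- function(vals) {
        q <- quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        sprintf("%g (%g, %g)", q[2], q[1], q[3])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "median (IQR)",
        group0 = fmt(x[ok & g == lv[1]]), group1 = fmt(x[ok & g == lv[2]]),
        statistic = as.numeric(test$statistic), p_value = test$p.value,
        p_display = format_p(test$p.value), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "group0"] <- paste0(group, " = ", lv[1])
  names(out)[names(out) == "group1"] <- paste0(group, " = ", lv[2])
  rownames(out) <- NULL
  out
}

format_p <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "<0.001" else format(signif(p, 2), scientific = FALSE)
}

default_hp_grid <- function(seed = 1L) {
  grid <- list()
  for (md in c(2L, 3L)) {
    for (msl in c(50L, 150L)) {
      for (cp in c(0, 5e-5)) {
        grid[[length(grid) + 1L]] <- tree_hyperparameters(
          max_depth = md, min_samples_leaf = msl, cp = cp, seed = seed)
      }
    }
  }
  grid
}

#' Pipeline configuration
#'
#' @param synthetic A [synthetic_config()] to simulate the input cohort, or
#'   `NULL` when `input_csv` is given.
#' @param input_csv Path to a raw encounter CSV (alternative to
#'   `synthetic`).
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory for artifacts (`NULL` = no files).
#' @param imputer_k Imputer neighbour count.
#' @param n_folds Cross-fitting folds for nuisance models.
#' @param num_trees Trees per forest.
#' @param eps Propensity clip bound.
#' @param grid Hyperparameter grid (list of [tree_hyperparameters()]).
#' @param cv_folds Grid-search cross-validation folds.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), input_csv = NULL,
                            seed = 1L, out_dir = NULL, imputer_k = 10L,
                            n_folds = 5L, num_trees = 200L, eps = 0.05,
                            grid = default_hp_grid(seed), cv_folds = 3L) {
  if (is.null(synthetic) && is.null(input_csv)) {
    stop("configuration error: provide synthetic config or input_csv",
         call. = FALSE)
  }
  if (!is.null(input_csv) && !file.exists(input_csv)) {
    stop(sprintf("configuration error: input_csv does not exist: %s",
                 input_csv), call. = FALSE)
  }
  structure(list(synthetic = synthetic, input_csv = input_csv,
                 seed = as.integer(seed), out_dir = out_dir,
                 imputer_k = as.integer(imputer_k),
                 n_folds = as.integer(n_folds),
                 num_trees = as.integer(num_trees), eps = eps, grid = grid,
                 cv_folds = as.integer(cv_folds)),
            class = "pipeline_config")
}

#' Run the full prescription pipeline
#'
#' Stages, in order: cohort construction (simulate or load), study filters
#' with attrition log, treatment labelling from procedure codes, trauma-bay
#' feature derivation, stratified 50:50 split, training-half imputation and
#' cross-fitted nuisance fits, doubly-robust training rewards, grid search,
#' greedy growth plus local search, test-half reward re-estimation, and
#' off-policy evaluation. Rerunning with the same configuration reproduces
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return List with the cohort, attrition log, split halves, CV table,
#'   fitted tree, test-side rewards, evaluation report, descriptive table,
#'   and nuisance AUCs.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seed <- config$seed

  say("[1/5] cohort construction and study filters")
  truth <- NULL
  raw <- stage("cohort", {
    if (!is.null(config$input_csv)) {
      read.csv(config$input_csv, stringsAsFactors = TRUE)
    } else {
      sim <- generate_cohort(config$synthetic)
      truth <- sim$truth
      sim$cohort
    }
  })
  flt <- stage("filters", apply_study_filters(raw))
  cohort <- flt$cohort
  if ("procedure_codes" %in% names(cohort)) {
    cohort$reboa <- stage("treatment labelling",
                          label_reboa(cohort$procedure_codes))
  }
  if (!all(c("reboa", "death_24h") %in% names(cohort))) {
    stop("pipeline stage 'treatment labelling' failed: cohort lacks reboa/death_24h",
         call. = FALSE)
  }
  if (!is.null(truth)) truth <- truth[truth$id %in% cohort$id, , drop = FALSE]

  say("[2/5] imputation (training half)")
  feats <- stage("feature derivation", derive_features(cohort))
  halves <- stage("split", split_cohort(feats, seed = seed))
  imp <- stage("imputation", fit_imputer(halves$train, k = config$imputer_k,
                                         seed = seed))
  train_tab <- stage("imputation", impute_table(imp, halves$train))
  X_train <- train_tab[, intersect(MODEL_COVARIATES, names(train_tab)),
                       drop = FALSE]

  say("[3/5] reward estimation (cross-fitted forests, DR)")
  nuis <- stage("reward estimation",
                fit_nuisance(X_train, halves$train$reboa,
                             halves$train$death_24h,
                             n_folds = config$n_folds, eps = config$eps,
                             num_trees = config$num_trees, seed = seed + 1L))
  nuis$fitted_on <- "train-half"
  rewards_train <- doubly_robust_rewards(nuis, halves$train$reboa,
                                         halves$train$death_24h)

  say("[4/5] policy-tree training (grid search + local search)")
  gs <- stage("grid search",
              grid_search_hyperparams(rewards_train, X_train, config$grid,
                                      n_folds = config$cv_folds,
                                      seed = seed + 2L))
  tree <- stage("tree growth", {
    t0 <- grow_policy_tree(rewards_train, X_train, gs$best)
    local_search(t0, rewards_train, X_train, gs$best)
  })

  say("[5/5] test-half reward re-estimation and policy evaluation")
  test_side <- stage("test rewards",
                     estimate_test_rewards(halves$test,
                                           n_folds = config$n_folds,
                                           k = config$imputer_k,
                                           num_trees = config$num_trees,
                                           eps = config$eps,
                                           seed = seed + 3L))
  evaluation <- stage("evaluation",
                      evaluate_policy(tree, test_side$rewards, test_side$X))

  descriptive <- stage("descriptive table", {
    vars <- c("age", "sbp", "pulse", "gcs", "pelvic_fx", "pneumothorax",
              "hemothorax", "death_24h")
    vars <- intersect(vars, names(cohort))
    kinds <- setNames(ifelse(vars %in% c("pelvic_fx", "pneumothorax",
                                         "hemothorax", "death_24h"),
                             "categorical", "continuous"), vars)
    compare_groups(cohort, "reboa", vars, kinds)
  })

  result <- list(cohort = cohort, truth = truth, attrition = flt$attrition,
                 train = halves$train, test = halves$test, cv = gs$cv,
                 hyperparameters = gs$best, tree = tree,
                 train_rewards = rewards_train, test_side = test_side,
                 evaluation = evaluation, descriptive = descriptive,
                 train_auc = nuisance_auc(nuis, halves$train$reboa,
                                          halves$train$death_24h),
                 config = config)

  if (!is.null(config$out_dir)) {
    write_pipeline_artifacts(result, config$out_dir)
  }
  result
}

write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_attrition(result$attrition, file.path(dir, "attrition.json"),
                  file.path(dir, "attrition.txt"))
  write.csv(result$cv, file.path(dir, "cv_table.csv"), row.names = FALSE)
  writeLines(policy_tree_json(result$tree), file.path(dir, "tree.json"))
  writeLines(policy_tree_dot(result$tree), file.path(dir, "tree.dot"))
  ev <- result$evaluation
  jsonlite::write_json(
    list(overall = ev$overall, groups = ev$groups, leaves = ev$leaves),
    file.path(dir, "evaluation.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE)
  write.csv(format_leaf_table(ev), file.path(dir, "leaf_arr_table.csv"),
            row.names = FALSE)
  write.csv(ev$groups, file.path(dir, "arr_by_group.csv"), row.names = FALSE)
  write.csv(cbind(id = result$test$id, result$test_side$rewards),
            file.path(dir, "test_rewards.csv"), row.names = FALSE)
  write.csv(result$descriptive, file.path(dir, "descriptive_table.csv"),
            row.names = FALSE)
  invisible(dir)
}
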