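# k-nearest-neighbour imputation of trauma-bay covariates.
#
# Distances are standardized Euclidean over the numerics co-observed between
# the target row and the donor pool of fully-complete training rows; numeric
# gaps take the mean of the k nearest donors, categorical gaps the donor-set
# mode (lexicographic tie-break). Rows with no usable distance fall back to
# the per-feature training median/mode. Observed cells are never altered.

imputer_feature_kinds <- function(train, features) {
  vapply(features, function(f) {
    x <- train[[f]]
    if (is.factor(x) || is.character(x) || is.logical(x)) return("categorical")
    obs <- x[!is.na(x)]
    if (length(obs) && all(obs %in% c(0, 1))) return("categorical")
    "numeric"
  }, character(1))
}

#' Fit a k-nearest-neighbour imputer on training rows
#'
#' @param train Training cohort data.frame (bookkeeping columns `id`,
#'   `reboa`, `death_24h` are ignored).
#' @param k Number of donor neighbours (default 10).
#' @param seed Integer seed (kept for interface stability; the fit is fully
#'   deterministic).
#' @param features Character vector of covariates to model; defaults to the
#'   trauma-bay covariate set present in `train`.
#' @return An object of class `knn_imputer`.
#' @export
fit_imputer <- function(train, k = 10L, seed = 1L,
                        features = intersect(MODEL_COVARIATES, names(train))) {
  if (!nrow(train)) stop("fit error: empty training table", call. = FALSE)
  if (k < 1) stop("fit error: k must be >= 1", call. = FALSE)
  all_missing <- features[vapply(features,
                                 function(f) all(is.na(train[[f]])),
                                 logical(1))]
  if (length(all_missing)) {
    stop(sprintf("fit error: feature(s) entirely missing: %s",
                 paste(all_missing, collapse = ", ")), call. = FALSE)
  }
  kinds <- imputer_feature_kinds(train, features)
  numerics <- features[kinds == "numeric"]
  categoricals <- features[kinds == "categorical"]

  center <- vapply(numerics, function(f) mean(train[[f]], na.rm = TRUE),
                   numeric(1))
  scale <- vapply(numerics, function(f) {
    s <- sd(train[[f]], na.rm = TRUE)
    if (!is.finite(s) || s == 0) 1 else s
  }, numeric(1))

  fallback_num <- vapply(numerics,
                         function(f) median(train[[f]], na.rm = TRUE),
                         numeric(1))
  fallback_cat <- vapply(categoricals, function(f) {
    lex_mode(as.character(train[[f]][!is.na(train[[f]])]))
  }, character(1))

  complete <- complete.cases(train[, features, drop = FALSE])
  donors <- train[complete, features, drop = FALSE]
  donor_num <- if (length(numerics)) {
    sweep(sweep(as.matrix(donors[, numerics, drop = FALSE]), 2, center),
          2, scale, "/")
  } else {
    matrix(numeric(0), nrow(donors), 0)
  }

  structure(list(
    features = features, kinds = kinds, numerics = numerics,
    categoricals = categoricals, center = center, scale = scale,
    fallback_num = fallback_num, fallback_cat = fallback_cat,
    donors = donors, donor_num = donor_num, k = as.integer(k),
    seed = as.integer(seed)
  ), class = "knn_imputer")
}

# Most frequent value; ties broken lexicographically for determinism.
lex_mode <- function(x) {
  tab <- table(x)
  names(tab)[order(-as.numeric(tab), names(tab))][1]
}

#' Impute missing covariates with a fitted kNN model
#'
#' @param model A `knn_imputer` from [fit_imputer()].
#' @param table Data.frame whose covariate schema matches the model.
#' @return `table` with all model covariates complete; observed cells are
#'   unchanged.
#' @export
impute_table <- function(model, table) {
  stopifnot(inherits(model, "knn_imputer"))
  absent <- setdiff(model$features, names(table))
  if (length(absent)) {
    stop(sprintf("schema error: table lacks feature(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  out <- table
  feats <- model$features
  miss_mat <- vapply(feats, function(f) is.na(table[[f]]),
                     logical(nrow(table)))
  if (!is.matrix(miss_mat)) miss_mat <- matrix(miss_mat, nrow = nrow(table))
  target_rows <- which(rowSums(miss_mat) > 0)
  if (!length(target_rows)) return(out)

  numerics <- model$numerics
  n_donor <- nrow(model$donors)
  if (length(numerics)) {
    Z <- sweep(sweep(as.matrix(table[, numerics, drop = FALSE]), 2,
                     model$center), 2, model$scale, "/")
  } else {
    Z <- matrix(numeric(0), nrow(table), 0)
  }

  # Group target rows by their observed-numeric pattern; each group shares
  # one distance computation against the donor matrix.
  obs_num <- !is.na(Z[target_rows, , drop = FALSE])
  key <- apply(obs_num, 1, function(r) paste(as.integer(r), collapse = ""))
  if (!length(numerics)) key <- rep("", length(target_rows))

  for (kk in unique(key)) {
    rows <- target_rows[key == kk]
    S <- if (nzchar(kk)) which(strsplit(kk, "")[[1]] == "1") else integer(0)
    if (!length(S) || n_donor == 0) {
      out <- impute_fallback(model, out, rows, miss_mat, feats)
      next
    }
    nn <- nearest_donors(Z[rows, S, drop = FALSE],
                         model$donor_num[, S, drop = FALSE], model$k)
    for (j in seq_along(rows)) {
      r <- rows[j]
      idx <- nn[[j]]
      for (f in feats[miss_mat[r, ]]) {
        if (f %in% numerics) {
          out[[f]][r] <- mean(model$donors[[f]][idx])
        } else {
          out[[f]][r] <- coerce_like(
            lex_mode(as.character(model$donors[[f]][idx])), out[[f]])
        }
      }
    }
  }
  out
}

impute_fallback <- function(model, out, rows, miss_mat, feats) {
  for (r in rows) {
    for (f in feats[miss_mat[r, ]]) {
      if (f %in% model$numerics) {
        out[[f]][r] <- model$fallback_num[[f]]
      } else {
        out[[f]][r] <- coerce_like(model$fallback_cat[[f]], out[[f]])
      }
    }
  }
  out
}

coerce_like <- function(value, column) {
  if (is.factor(column)) return(value)   # assigned as level label
  if (is.logical(column)) return(as.logical(value))
  if (is.numeric(column)) return(as.numeric(value))
  value
}

# k nearest donor indices per target row (squared standardized Euclidean
# distance over the shared observed numerics); ties break to the lower donor
# index via order()'s stable radix sort. Chunked to bound memory.
nearest_donors <- function(A, B, k, chunk = 512L) {
  n <- nrow(A)
  d <- nrow(B)
  k <- min(k, d)
  b2 <- rowSums(B^2)
  res <- vector("list", n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    Ai <- A[idx, , drop = FALSE]
    D2 <- outer(rowSums(Ai^2), b2, "+") - 2 * tcrossprod(Ai, B)
    for (j in seq_along(idx)) {
      res[[idx[j]]] <- order(D2[j, ])[seq_len(k)]
    }
  }
  res
}
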