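#' Hyperparameters for the bagged-tree ensemble
#'
#' The ensemble classification model is parameterized by the number of
#' bagged trees (`n_learning_cycles`), the per-tree split budget
#' (`max_num_splits`) and the minimum weighted leaf size (`min_leaf_size`,
#' fixed at 5 in the study setting).
#'
#' @param n_learning_cycles Number of bootstrap trees (>= 1).
#' @param max_num_splits Maximum splits per tree; `NULL` means `n - 1` at
#'   fit time (unrestricted).
#' @param min_leaf_size Minimum observations per leaf.
#' @return An object of class `ensemble_hyperparams`.
#' @export
ensemble_hyperparams <- function(n_learning_cycles = 200,
                                 max_num_splits = NULL,
                                 min_leaf_size = 5) {
  if (!is_count(n_learning_cycles) || !is_count(min_leaf_size) ||
      (!is.null(max_num_splits) && !is_count(max_num_splits))) {
    stopf("ensemble hyperparameters must be positive integers")
  }
  structure(list(n_learning_cycles = as.integer(n_learning_cycles),
                 max_num_splits = if (is.null(max_num_splits)) NULL else
                   as.integer(max_num_splits),
                 min_leaf_size = as.integer(min_leaf_size)),
            class = "ensemble_hyperparams")
}

#' @export
print.ensemble_hyperparams <- function(x, ...) {
  cat(sprintf("Ensemble hyperparameters: %d trees, max %s splits, min leaf %d\n",
              x$n_learning_cycles,
              if (is.null(x$max_num_splits)) "n-1" else x$max_num_splits,
              x$min_leaf_size))
  invisible(x)
}

#' Train a bagged decision-tree ensemble
#'
#' Fits `n_learning_cycles` CART classification trees, each on a bootstrap
#' resample (n draws with replacement, realized as per-row weights), split
#' by Gini impurity under the `max_num_splits` best-first split budget and
#' `min_leaf_size` constraint. Class posteriors for new data are the mean of
#' the per-tree leaf class frequencies. Deterministic given `seed`.
#'
#' @param train Labelled feature table; at least two classes must be present.
#' @param features Character vector of feature columns to use.
#' @param hp An [ensemble_hyperparams()].
#' @param seed Integer seed for the bootstrap draws.
#' @return An object of class `bagged_tree_ensemble`.
#' @export
train_bagged_ensemble <- function(train, features = feature_columns(train),
                                  hp = ensemble_hyperparams(), seed = 1) {
  stopifnot(inherits(hp, "ensemble_hyperparams"))
  y <- outcome_of(train)
  y <- droplevels(y)
  if (nlevels(y) < 2) stopf("training data contain a single class")
  miss <- setdiff(features, names(train))
  if (length(miss)) stopf("features not in table: %s", paste(miss, collapse = ", "))
  X <- as.matrix(train[features])
  if (anyNA(X)) stopf("missing values in features")
  n <- nrow(X)
  max_splits <- hp$max_num_splits %||% (n - 1L)
  trees <- with_seed(seed, lapply(seq_len(hp$n_learning_cycles), function(t) {
    w <- tabulate(sample.int(n, n, replace = TRUE), n)
    .grow_tree_cpp(X, as.integer(y) - 1L, nlevels(y), as.numeric(w),
                   as.integer(max_splits), as.numeric(hp$min_leaf_size))
  }))
  structure(list(trees = trees, features = features,
                 class_levels = levels(y), hp = hp, seed = seed,
                 n_train = n),
            class = "bagged_tree_ensemble")
}

#' @export
print.bagged_tree_ensemble <- function(x, ...) {
  cat(sprintf("Bagged tree ensemble: %d trees on %d features (n = %d), classes %s\n",
              length(x$trees), length(x$features), x$n_train,
              paste(x$class_levels, collapse = "/")))
  invisible(x)
}

#' Predict from a bagged-tree ensemble
#'
#' @param object A [train_bagged_ensemble()] fit.
#' @param newdata Feature table containing the model's features.
#' @param type `"prob"` for class posteriors (rows sum to 1), `"class"` for
#'   the posterior-maximizing label (first class wins ties).
#' @param ... Unused.
#' @return A numeric matrix (`prob`) or factor (`class`).
#' @export
predict.bagged_tree_ensemble <- function(object, newdata,
                                         type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[object$features])
  post <- .predict_ensemble_cpp(object$trees, X)
  colnames(post) <- object$class_levels
  if (type == "prob") return(post)
  factor(object$class_levels[max.col(post, ties.method = "first")],
         levels = object$class_levels)
}

#' Impurity-based predictor importance
#'
#' Total Gini impurity decrease attributed to each feature, summed over the
#' splits that use it, averaged over trees, and normalized to sum to 1.
#' Features never used in a split score 0.
#'
#' @param model A [train_bagged_ensemble()] fit.
#' @return Named numeric vector over the model's features.
#' @export
predictor_importance <- function(model) {
  stopifnot(inherits(model, "bagged_tree_ensemble"))
  imp <- rowMeans(vapply(model$trees, function(tr) tr$importance,
                         numeric(length(model$features))))
  names(imp) <- model$features
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  imp
}

#' Tune ensemble hyperparameters by seeded random search
#'
#' Samples `budget` configurations from log-uniform grids —
#' `n_learning_cycles` in `[10, 500]`, `max_num_splits` in `[1, n - 1]` —
#' and scores each by stratified inner cross-validated multiclass log-loss,
#' with `min_leaf_size` fixed at 5. The best-scoring draw wins (first on
#' ties). Deterministic given `seed`.
#'
#' @param train Labelled feature table.
#' @param features Feature columns to use.
#' @param budget Number of random draws (>= 1).
#' @param seed Integer seed.
#' @param inner_folds Inner CV folds (default 3, truncated to the smallest
#'   class).
#' @return An [ensemble_hyperparams()]; if no draw yields a valid fit, the
#'   documented defaults (200 cycles, `n - 1` splits) with a warning.
#' @export
tune_hyperparams <- function(train, features = feature_columns(train),
                             budget = 30, seed = 1, inner_folds = 3) {
  if (!is_count(budget)) stopf("budget must be a positive integer")
  y <- outcome_of(train)
  n <- nrow(train)
  k <- max(2L, min(inner_folds, min(table(droplevels(y)))))
  draws <- with_seed(seed, data.frame(
    n_learning_cycles = pmax(10L, pmin(500L, as.integer(round(
      exp(stats::runif(budget, log(10), log(500))))))),
    max_num_splits = pmax(1L, pmin(n - 1L, as.integer(round(
      exp(stats::runif(budget, log(1), log(n - 1)))))))))
  folds <- stratified_folds(train, cv_scheme(n_folds = k, n_repeats = 1,
                                             seed = derive_seed(seed, 1)))[[1]]
  scores <- vapply(seq_len(budget), function(d) {
    hp <- ensemble_hyperparams(draws$n_learning_cycles[d],
                               draws$max_num_splits[d], 5)
    tryCatch({
      ll <- 0
      for (f in seq_len(k)) {
        tr <- train[folds != f, , drop = FALSE]
        te <- train[folds == f, , drop = FALSE]
        fit <- train_bagged_ensemble(tr, features, hp,
                                     seed = derive_seed(seed, d, f))
        post <- predict(fit, te, type = "prob")
        p_true <- post[cbind(seq_len(nrow(te)),
                             match(as.character(te$outcome), colnames(post)))]
        p_true[is.na(p_true)] <- 0  # class absent from the training fold
        ll <- ll + sum(-log(pmax(p_true, 1e-15)))
      }
      ll / n
    }, error = function(e) Inf)
  }, numeric(1))
  if (all(!is.finite(scores))) {
    warning("hyperparameter search found no valid fit; using defaults",
            call. = FALSE)
    return(ensemble_hyperparams(200, n - 1L, 5))
  }
  best <- which.min(scores)
  hp <- ensemble_hyperparams(draws$n_learning_cycles[best],
                             draws$max_num_splits[best], 5)
  attr(hp, "search") <- cbind(draws, log_loss = scores)
  hp
}
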