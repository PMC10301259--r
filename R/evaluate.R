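#' Evaluate the nested model series under repeated stratified CV
#'
#' For every feature subset in the series and every train/test split of the
#' scheme (5 folds x 10 repeats = 50 splits in the study protocol), trains
#' the bagged ensemble on the training split, scores the test split, and
#' records the macro-averaged one-vs-rest AUC plus per-class true positive
#' rates and overall accuracy at two operating points: the default cutoff
#' 0.5, and per-class Youden-optimal cutoffs. Cutoffs are estimated on the
#' training split and applied to the test split when
#' `cutoff_mode = "train"` (honest default); `"pooled"` estimates them on
#' the pooled test scores of each split instead.
#'
#' Accuracies are averaged per fold (each split contributes one value, then
#' the 50 values are averaged), reported in percent.
#'
#' @param series A [build_nested_models()] result.
#' @param table Labelled feature table the series was built for.
#' @param scheme A [cv_scheme()].
#' @param seed Integer seed for the per-split training randomness.
#' @param tune_mode `"fast"` reuses each subset's hyperparameters from the
#'   series across all splits; `"per_fold"` re-tunes on every training
#'   split (50x the tuning cost).
#' @param hp_budget Random-search budget when tuning is needed.
#' @param cutoff_mode Where optimal cutoffs are estimated (see above).
#' @return An object of class `model_evaluation_list`: one
#'   `model_evaluation` per subset, each with `feature_count`, `features`,
#'   `auc_samples` (one macro AUC per split), `auc_mean`, `auc_sd`,
#'   `default` and `optimal` blocks (per-class TPR %, overall %), and the
#'   mean per-class optimal cutoffs.
#' @export
evaluate_model_series <- function(series, table, scheme = cv_scheme(),
                                  seed = 1,
                                  tune_mode = c("fast", "per_fold"),
                                  hp_budget = 30,
                                  cutoff_mode = c("train", "pooled")) {
  stopifnot(inherits(series, "nested_model_series"))
  tune_mode <- match.arg(tune_mode)
  cutoff_mode <- match.arg(cutoff_mode)
  y <- droplevels(outcome_of(table))
  classes <- levels(y)
  folds <- stratified_folds(table, scheme)
  sizes <- rev(seq_along(series$subsets))  # evaluate large models first
  evals <- vector("list", length(series$subsets))

  for (k in sizes) {
    feats <- series$subsets[[k]]
    hp_fast <- series$hp[[k]] %||% ensemble_hyperparams()
    n_split <- scheme$n_repeats * scheme$n_folds
    auc_samples <- numeric(n_split)
    tpr_def <- tpr_opt <- matrix(NA_real_, n_split, length(classes),
                                 dimnames = list(NULL, classes))
    acc_def <- acc_opt <- numeric(n_split)
    cut_opt <- matrix(NA_real_, n_split, length(classes),
                      dimnames = list(NULL, classes))
    s <- 0L
    for (r in seq_len(scheme$n_repeats)) {
      fold <- folds[[r]]
      for (f in seq_len(scheme$n_folds)) {
        s <- s + 1L
        tr <- table[fold != f, , drop = FALSE]
        te <- table[fold == f, , drop = FALSE]
        hp <- if (tune_mode == "per_fold") {
          tune_hyperparams(tr, feats, budget = hp_budget,
                           seed = derive_seed(seed, k, r, f, 1))
        } else {
          hp_fast
        }
        fit <- train_bagged_ensemble(tr, feats, hp,
                                     seed = derive_seed(seed, k, r, f, 2))
        post_te <- predict(fit, te, type = "prob")
        y_te <- as.character(te$outcome)
        roc_te <- roc_multiclass(post_te, y_te, classes)
        auc_samples[s] <- roc_te$macro_auc

        pred_def <- classify_at_cutoff(post_te, 0.5)
        cut_source <- if (cutoff_mode == "train") {
          list(post = predict(fit, tr, type = "prob"),
               labels = as.character(tr$outcome))
        } else {
          list(post = post_te, labels = y_te)
        }
        cuts <- vapply(classes, function(cl) {
          r_cl <- roc_curve(cut_source$post, cut_source$labels, cl)
          if (!r_cl$defined) return(0.5)
          optimal_cutoff(r_cl)
        }, numeric(1))
        pred_opt <- classify_at_cutoff(post_te, cuts)
        cut_opt[s, ] <- cuts

        for (cl in classes) {
          in_cl <- y_te == cl
          if (any(in_cl)) {
            tpr_def[s, cl] <- mean(pred_def[in_cl] == cl)
            tpr_opt[s, cl] <- mean(pred_opt[in_cl] == cl)
          }
        }
        acc_def[s] <- mean(pred_def == y_te)
        acc_opt[s] <- mean(pred_opt == y_te)
      }
    }
    evals[[k]] <- structure(list(
      feature_count = length(feats),
      features = feats,
      auc_samples = auc_samples,
      auc_mean = mean(auc_samples),
      auc_sd = stats::sd(auc_samples),
      default = list(per_class_tpr = 100 * colMeans(tpr_def, na.rm = TRUE),
                     overall = 100 * mean(acc_def)),
      optimal = list(per_class_tpr = 100 * colMeans(tpr_opt, na.rm = TRUE),
                     overall = 100 * mean(acc_opt),
                     cutoffs = colMeans(cut_opt, na.rm = TRUE)),
      classes = classes,
      cutoff_mode = cutoff_mode,
      tune_mode = tune_mode),
      class = "model_evaluation")
  }
  structure(evals, class = "model_evaluation_list")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("Model with %d feature(s): AUC %.3f +- %.3f (n = %d splits)\n",
              x$feature_count, x$auc_mean, x$auc_sd, length(x$auc_samples)))
  cat(sprintf("  overall accuracy: %.1f%% (default cutoff) / %.1f%% (optimal)\n",
              x$default$overall, x$optimal$overall))
  invisible(x)
}

#' @export
print.model_evaluation_list <- function(x, ...) {
  cat(sprintf("Evaluations for %d nested models\n", length(x)))
  for (e in rev(x)) {
    cat(sprintf("  %2d features: AUC %.3f, overall %.1f%% / %.1f%%\n",
                e$feature_count, e$auc_mean, e$default$overall,
                e$optimal$overall))
  }
  invisible(x)
}

#' One-way ANOVA across model AUC distributions
#'
#' Standard one-way fixed-effects ANOVA (via [stats::aov()]) comparing the
#' per-split AUC samples across models. Degenerate inputs follow the
#' conventions: all-equal group means give F = 0, p = 1; zero within-group
#' variance with unequal means gives F = Inf, p = 0.
#'
#' @param groups List of numeric vectors (one per model), or a matrix with
#'   one column per model. Every group needs >= 2 values.
#' @return List with `f`, `p`, `df_between`, `df_within`.
#' @export
anova_one_way <- function(groups) {
  if (is.matrix(groups)) groups <- asplit(groups, 2)
  if (is.data.frame(groups)) groups <- as.list(groups)
  if (!is.list(groups) || length(groups) < 2) stopf("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stopf("every group needs >= 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  grand <- mean(values)
  ssb <- sum(sizes * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum((values - rep(vapply(groups, mean, numeric(1)), sizes))^2)
  df_b <- length(groups) - 1L
  df_w <- length(values) - length(groups)
  if (ssw <= 1e-300) {
    if (ssb <= 1e-300) return(list(f = 0, p = 1, df_between = df_b,
                                   df_within = df_w))
    return(list(f = Inf, p = 0, df_between = df_b, df_within = df_w))
  }
  tab <- summary(stats::aov(values ~ g))[[1]]
  list(f = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       df_between = df_b, df_within = df_w)
}

#' Paired t-test on per-split metric differences
#'
#' Two-sided paired t-test (via [stats::t.test()]) between two models'
#' per-split values. A zero-variance difference vector is handled
#' explicitly: identical samples give t = 0, p = 1; a constant non-zero
#' difference gives t = +-Inf with p = 0.
#'
#' @param a,b Numeric vectors of equal length, paired by split.
#' @return List with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stopf("paired samples must have equal length")
  if (length(a) < 2) stopf("need >= 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = length(d) - 1L,
                                  mean_diff = 0))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1L,
                mean_diff = mean(d)))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = unname(ht$estimate))
}

#' Pairwise post-hoc paired t-tests across models
#'
#' All model pairs compared by [paired_ttest()] on their AUC samples. No
#' multiple-testing correction is applied by default; set
#' `adjust = "bonferroni"` (or any [stats::p.adjust()] method) to correct.
#'
#' @param evals A [evaluate_model_series()] result.
#' @param adjust p-value adjustment method (default `"none"`).
#' @return `data.frame` with columns `model_a`, `model_b`, `t`, `p`.
#' @export
pairwise_model_tests <- function(evals, adjust = "none") {
  stopifnot(inherits(evals, "model_evaluation_list"))
  ks <- vapply(evals, function(e) as.integer(e$feature_count), integer(1))
  pairs <- utils::combn(seq_along(evals), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tt <- paired_ttest(evals[[i1]]$auc_samples, evals[[i2]]$auc_samples)
    data.frame(model_a = ks[i1], model_b = ks[i2], t = tt$t, p = tt$p)
  }))
  out$p <- stats::p.adjust(out$p, method = adjust)
  out
}

#' Select the best and the optimal model
#'
#' Best = maximum mean AUC (ties go to the model with fewer features).
#' Optimal = the model with the fewest features whose mean AUC exceeds
#' 0.95 x the maximum.
#'
#' @param evals A [evaluate_model_series()] result.
#' @param comparable_fraction The "comparable AUC" multiplier (0.95).
#' @return List with `best` and `optimal` (feature counts), `max_auc`, and
#'   the comparability `threshold`.
#' @export
select_best_and_optimal <- function(evals, comparable_fraction = 0.95) {
  stopifnot(inherits(evals, "model_evaluation_list"))
  ks <- vapply(evals, function(e) as.integer(e$feature_count), integer(1))
  means <- vapply(evals, function(e) e$auc_mean, numeric(1))
  ord <- order(ks)
  ks <- ks[ord]; means <- means[ord]
  max_auc <- max(means)
  best <- ks[which(means == max_auc)[1]]  # smallest feature count on ties
  thr <- comparable_fraction * max_auc
  ok <- which(means > thr)
  optimal <- ks[ok[1]]
  list(best = best, optimal = optimal, max_auc = max_auc, threshold = thr)
}
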