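#' Multiclass ReliefF feature ranking
#'
#' Scores each feature by how well it separates near neighbours of different
#' classes. For every instance the `k_neighbors` nearest hits (same class)
#' and, for each other class, the `k_neighbors` nearest misses are located
#' under Manhattan distance on range-normalized features; a feature's weight
#' decreases with its mean normalized difference to the hits and increases
#' with its prior-weighted mean difference to the misses. All instances are
#' used (no subsampling) and weights are averaged over instances, so weights
#' lie in `[-1, 1]`.
#'
#' Range normalization makes the ranking invariant to affine rescaling of any
#' feature. Constant features contribute zero. If `k_neighbors` is not
#' available within a class, the neighbour count is truncated for that class
#' with a warning.
#'
#' @param table Labelled feature table (numeric features plus `outcome`).
#' @param k_neighbors Number of neighbours per class (default 10).
#' @return An object of class `relieff_ranking`: a `data.frame` with columns
#'   `feature` and `weight`, ordered by non-increasing weight (ties keep
#'   input feature order), with the `k_neighbors` used as an attribute.
#' @export
relieff_rank <- function(table, k_neighbors = 10) {
  y <- outcome_of(table)
  y <- droplevels(y)
  feats <- feature_columns(table)
  if (length(feats) < 1) stopf("need at least one feature")
  X <- as.matrix(table[feats])
  if (!is.numeric(X) || anyNA(X)) stopf("features must be numeric with no missing values")
  n <- nrow(X)
  if (n <= k_neighbors) stopf("need more instances (%d) than k_neighbors (%d)",
                              n, k_neighbors)
  rng <- apply(X, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1  # constant feature: all diffs are 0 anyway
  Xn <- sweep(X, 2, rng, "/")

  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  classes <- levels(y)
  prior <- table(y)[classes] / n
  cls_idx <- lapply(classes, function(cl) which(y == cl))
  names(cls_idx) <- classes

  sizes <- vapply(cls_idx, length, 0L)
  k_hit <- pmin(sizes - 1L, k_neighbors)
  k_miss <- pmin(sizes, k_neighbors)
  if (any(k_hit < k_neighbors) || any(k_miss < k_neighbors)) {
    small <- classes[k_hit < k_neighbors | k_miss < k_neighbors]
    warning(sprintf("k_neighbors = %d exceeds the size of class(es) %s; truncated",
                    k_neighbors, paste(small, collapse = ", ")),
            call. = FALSE)
  }

  w <- stats::setNames(numeric(length(feats)), feats)
  for (i in seq_len(n)) {
    ci <- as.character(y[i])
    for (cl in classes) {
      pool <- setdiff(cls_idx[[cl]], i)
      k <- if (cl == ci) k_hit[[cl]] else k_miss[[cl]]
      if (k < 1 || !length(pool)) next
      # nearest first; ties broken by row index (stable order)
      nb <- pool[order(D[i, pool], pool)][seq_len(min(k, length(pool)))]
      diffs <- abs(Xn[nb, , drop = FALSE] -
                     matrix(Xn[i, ], length(nb), ncol(Xn), byrow = TRUE))
      mean_diff <- colMeans(diffs)
      if (cl == ci) {
        w <- w - mean_diff / n
      } else {
        w <- w + (prior[[cl]] / (1 - prior[[ci]])) * mean_diff / n
      }
    }
  }
  ord <- order(-w, seq_along(w))
  structure(data.frame(feature = feats[ord], weight = unname(w[ord]),
                       check.names = FALSE),
            k_neighbors = k_neighbors,
            class = c("relieff_ranking", "data.frame"))
}

#' @export
print.relieff_ranking <- function(x, ...) {
  cat(sprintf("ReliefF ranking of %d features (k = %d)\n",
              nrow(x), attr(x, "k_neighbors")))
  print.data.frame(utils::head(x, 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Select the top-ranked fraction of features
#'
#' Keeps the `round(fraction * p)` highest-weight features (round half up),
#' preserving rank order. With the study's 40-feature pool and
#' `fraction = 0.5` this is the top-20 selection.
#'
#' @param ranking A [relieff_rank()] result.
#' @param fraction Fraction in `(0, 1]`.
#' @return Character vector of selected feature names, best first.
#' @export
select_top_fraction <- function(ranking, fraction = 0.5) {
  stopifnot(inherits(ranking, "relieff_ranking"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stopf("fraction must be in (0, 1]")
  }
  m <- floor(fraction * nrow(ranking) + 0.5)  # round half up
  m <- max(1L, min(nrow(ranking), m))
  as.character(ranking$feature[seq_len(m)])
}
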