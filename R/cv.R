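#' Repeated stratified cross-validation scheme
#'
#' The study protocol: 5-fold stratified splits (80% train / 20% test),
#' repeated 10 times, giving 50 train/test splits per model.
#'
#' @param n_folds Folds per repeat.
#' @param n_repeats Number of repeats.
#' @param seed Integer seed controlling all fold assignments.
#' @return An object of class `cv_scheme`.
#' @export
cv_scheme <- function(n_folds = 5, n_repeats = 10, seed = 1) {
  if (!is_count(n_folds) || n_folds < 2) stopf("n_folds must be >= 2")
  if (!is_count(n_repeats)) stopf("n_repeats must be a positive integer")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratified = TRUE, seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Stratified fold assignments
#'
#' Partitions the rows into `n_folds` folds per repeat, preserving class
#' proportions: each class is split as evenly as possible (per-fold class
#' counts differ by at most 1), and each class's remainder rows go to the
#' folds currently smallest overall, so total fold sizes also differ by at
#' most 1. Deterministic given the scheme seed.
#'
#' @param table Labelled feature table.
#' @param scheme A [cv_scheme()].
#' @return List of length `n_repeats`; each element an integer vector of
#'   fold ids (1..n_folds), one per row.
#' @export
stratified_folds <- function(table, scheme) {
  stopifnot(inherits(scheme, "cv_scheme"))
  y <- droplevels(outcome_of(table))
  counts <- table(y)
  if (any(counts < scheme$n_folds)) {
    stopf("class '%s' has %d rows, fewer than n_folds = %d",
          names(counts)[which.min(counts)], min(counts), scheme$n_folds)
  }
  k <- scheme$n_folds
  with_seed(scheme$seed, {
    lapply(seq_len(scheme$n_repeats), function(r) {
      fold <- integer(length(y))
      totals <- numeric(k)
      for (cl in names(sort(counts, decreasing = TRUE))) {
        idx <- sample(which(y == cl))
        base <- length(idx) %/% k
        extra <- length(idx) %% k
        quota <- rep(base, k)
        if (extra > 0) {
          # remainder rows go to the currently smallest folds
          grow <- order(totals, seq_len(k))[seq_len(extra)]
          quota[grow] <- quota[grow] + 1L
        }
        fold[idx] <- rep.int(seq_len(k), quota)
        totals <- totals + quota
      }
      fold
    })
  })
}
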