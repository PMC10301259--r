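# Independent oracles and small data builders used across the suite.

# Brute-force multiclass ReliefF: recomputes every pairwise distance from
# scratch with explicit loops (no distance matrix, no vectorized updates).
brute_relieff <- function(X, y, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  rng <- apply(X, 2, function(v) max(v) - min(v))
  rng[rng == 0] <- 1
  classes <- unique(y)
  prior <- vapply(classes, function(cl) mean(y == cl), numeric(1))
  names(prior) <- classes
  w <- rep(0, p)
  for (i in seq_len(n)) {
    di <- vapply(seq_len(n), function(j) sum(abs(X[i, ] - X[j, ]) / rng),
                 numeric(1))
    for (cl in classes) {
      pool <- setdiff(which(y == cl), i)
      kk <- min(k, length(pool))
      if (kk < 1) next
      nb <- pool[order(di[pool], pool)][seq_len(kk)]
      md <- rep(0, p)
      for (j in nb) md <- md + abs(X[i, ] - X[j, ]) / rng / kk
      if (cl == y[i]) {
        w <- w - md / n
      } else {
        w <- w + prior[[cl]] / (1 - prior[[y[i]]]) * md / n
      }
    }
  }
  names(w) <- colnames(X)
  w
}

# Mann-Whitney pairwise-concordance AUC (ties count 1/2).
mw_auc <- function(scores, is_pos) {
  sp <- scores[is_pos]
  sn <- scores[!is_pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Exhaustive Youden cutoff: max TPR - FPR over all candidate thresholds,
# ties resolved towards the lower threshold.
brute_youden <- function(scores, is_pos) {
  best_j <- -Inf
  best_t <- Inf
  for (t in c(Inf, sort(unique(scores), decreasing = TRUE))) {
    pred <- scores >= t
    j <- mean(pred[is_pos]) - mean(pred[!is_pos])
    if (j > best_j + 1e-12 || (abs(j - best_j) <= 1e-12 && t < best_t)) {
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, j = best_j)
}

# Three well-separated Gaussian blobs in `p` dimensions (only the first two
# coordinates carry class signal).
blob_table <- function(n_per_class = 100, p = 2, sd = 0.5, seed = 1) {
  centers <- list(no_fall = c(0, 0), L_fall = c(4, 0), E_fall = c(0, 4))
  set.seed(seed)
  rows <- lapply(names(centers), function(cl) {
    m <- matrix(stats::rnorm(n_per_class * p, 0, sd), n_per_class, p)
    m[, 1] <- m[, 1] + centers[[cl]][1]
    m[, 2] <- m[, 2] + centers[[cl]][2]
    m
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- paste0("f", seq_len(p))
  out$outcome <- factor(rep(names(centers), each = n_per_class),
                        levels = c("no_fall", "L_fall", "E_fall"))
  out
}

# Minimal labelled table with one perfectly separating feature and one pure
# noise feature.
separable_table <- function(n = 60, seed = 1) {
  set.seed(seed)
  out <- data.frame(
    signal = c(stats::rnorm(n / 2, 0, 0.3), stats::rnorm(n / 2, 5, 0.3)),
    noise = stats::rnorm(n),
    check.names = FALSE)
  out$outcome <- factor(rep(c("no_fall", "L_fall"), each = n / 2),
                        levels = c("no_fall", "L_fall", "E_fall"))
  out
}

# A single-subset model series, for evaluating one feature set in isolation.
single_series <- function(features, hp = ensemble_hyperparams(200)) {
  structure(list(subsets = list(features), models = list(NULL),
                 hp = list(hp), elimination = data.frame(),
                 selected = features, seed = 1),
            class = "nested_model_series")
}
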