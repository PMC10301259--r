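test_that("stratified folds partition the cohort evenly", {
  tab <- generate_feature_table(table1_spec(), seed = 1)
  scheme <- cv_scheme(5, 10, seed = 2)
  folds <- stratified_folds(tab, scheme)
  expect_length(folds, 10L)
  for (fold in folds) {
    sizes <- as.vector(table(fold))
    expect_true(all(sizes %in% c(59L, 60L)))  # ~20% test folds
    e_fall <- table(fold[tab$outcome == "E_fall"])
    expect_true(all(e_fall %in% c(4L, 5L)))
    no_fall <- table(fold[tab$outcome == "no_fall"])
    expect_true(max(no_fall) - min(no_fall) <= 1)
  }
  expect_identical(folds, stratified_folds(tab, scheme))
  small <- tab[c(which(tab$outcome == "no_fall")[1:10],
                 which(tab$outcome == "E_fall")[1:3]), ]
  expect_error(stratified_folds(small, cv_scheme(5, 1, seed = 1)),
               "E_fall.*fewer than")
})

test_that("ROC handles the perfect, null, and one-sided cases", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  labels <- c("L_fall", "L_fall", "L_fall", "no_fall", "no_fall", "no_fall")
  r <- roc_curve(scores, labels, "L_fall")
  expect_equal(r$auc, 1)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  expect_true(all(r$tpr >= 0 & r$tpr <= 1 & r$fpr >= 0 & r$fpr <= 1))

  set.seed(3)
  n <- 4000
  s <- runif(n)
  l <- sample(c("L_fall", "no_fall"), n, TRUE)
  expect_lt(abs(roc_curve(s, l, "L_fall")$auc - 0.5), 0.05)

  one_sided <- roc_curve(c(0.1, 0.9), c("L_fall", "L_fall"), "no_fall")
  expect_false(one_sided$defined)
  expect_true(is.na(one_sided$auc))
})

test_that("AUC equals the pairwise-concordance count on toy score sets", {
  cases <- list(
    list(s = c(0.9, 0.4, 0.6, 0.2), pos = c(TRUE, FALSE, TRUE, FALSE)),
    list(s = c(0.5, 0.5, 0.3, 0.8), pos = c(TRUE, FALSE, FALSE, TRUE)),
    list(s = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.35), pos = c(FALSE, FALSE, TRUE,
                                                       TRUE, TRUE, FALSE)))
  for (cs in cases) {
    labels <- ifelse(cs$pos, "L_fall", "no_fall")
    expect_equal(roc_curve(cs$s, labels, "L_fall")$auc,
                 mw_auc(cs$s, cs$pos), tolerance = 1e-12)
  }
  set.seed(4)
  s <- round(runif(40), 2)  # duplicated scores exercise tie handling
  pos <- runif(40) > 0.6
  labels <- ifelse(pos, "L_fall", "no_fall")
  expect_equal(roc_curve(s, labels, "L_fall")$auc, mw_auc(s, pos),
               tolerance = 1e-12)
})

test_that("monotone score transforms leave the AUC unchanged", {
  set.seed(5)
  s <- rnorm(60)
  labels <- ifelse(runif(60) > 0.5, "L_fall", "no_fall")
  base <- roc_curve(s, labels, "L_fall")$auc
  expect_equal(roc_curve(exp(s), labels, "L_fall")$auc, base,
               tolerance = 1e-12)
  expect_equal(roc_curve(5 * s - 2, labels, "L_fall")$auc, base,
               tolerance = 1e-12)
})

test_that("the optimal cutoff maximizes Youden's J, ties to the sensitive side", {
  # perfect classifier: the cutoff reaches TPR 1 at FPR 0
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1),
                 c("L_fall", "L_fall", "no_fall", "no_fall"), "L_fall")
  cut <- optimal_cutoff(r)
  expect_equal(cut, 0.8)
  i <- which(r$thresholds == cut)
  expect_equal(r$tpr[i], 1)
  expect_equal(r$fpr[i], 0)

  set.seed(6)
  for (rep in 1:5) {
    s <- round(runif(25), 1)
    pos <- runif(25) > 0.5
    if (!any(pos) || all(pos)) next
    labels <- ifelse(pos, "L_fall", "no_fall")
    roc <- roc_curve(s, labels, "L_fall")
    expect_equal(optimal_cutoff(roc), brute_youden(s, pos)$threshold)
    # J-optimality: no threshold on the curve beats the returned one
    j <- roc$tpr - roc$fpr
    expect_equal(max(j), brute_youden(s, pos)$j, tolerance = 1e-12)
  }

  set.seed(7)
  s <- runif(5000)
  labels <- sample(c("L_fall", "no_fall"), 5000, TRUE)
  roc <- roc_curve(s, labels, "L_fall")
  expect_lt(max(roc$tpr - roc$fpr), 0.08)  # null J near zero at large n
})

test_that("cutoff classification follows the margin rule", {
  post <- rbind(c(0.8, 0.1, 0.1),
                c(0.4, 0.35, 0.25),
                c(1 / 3, 1 / 3, 1 / 3),
                c(0.2, 0.5, 0.3))
  colnames(post) <- c("no_fall", "L_fall", "E_fall")
  pred <- classify_at_cutoff(post, 0.5)
  expect_equal(as.character(pred), c("no_fall", "no_fall", "no_fall",
                                     "L_fall"))
  # per-class cutoffs: a low E_fall cutoff pulls the prediction over
  pred2 <- classify_at_cutoff(post, c(no_fall = 0.9, L_fall = 0.9,
                                      E_fall = 0.05))
  expect_equal(as.character(pred2[1]), "E_fall")
})

test_that("overall accuracy is the prevalence-weighted mean of class TPRs", {
  expect_equal(round(overall_accuracy(c(90.9, 38.9, 88.4),
                                      c(192, 22, 84)), 1), 86.4)
  expect_equal(overall_accuracy(c(100, 100, 100), c(192, 22, 84)), 100)
  expect_equal(round(overall_accuracy(c(100, 0, 0), c(192, 22, 84)), 1), 64.4)
})

test_that("one-way ANOVA matches its identities and degenerate conventions", {
  # textbook 3 x 5 example, F computed by hand from the SS decomposition
  g <- list(c(6, 8, 4, 5, 3), c(8, 12, 9, 11, 6), c(13, 9, 11, 8, 7))
  res <- anova_one_way(g)
  all_v <- unlist(g)
  grand <- mean(all_v)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 0))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  f_hand <- (ssb / 2) / (ssw / 12)
  expect_equal(res$f, f_hand, tolerance = 1e-12)
  expect_equal(res$p, stats::pf(f_hand, 2, 12, lower.tail = FALSE),
               tolerance = 1e-12)

  # two groups: F equals the square of the pooled two-sample t statistic
  set.seed(8)
  a <- rnorm(20); b <- rnorm(20, 0.7)
  res2 <- anova_one_way(list(a, b))
  t2 <- unname(stats::t.test(a, b, var.equal = TRUE)$statistic^2)
  expect_equal(res2$f, t2, tolerance = 1e-10)

  expect_equal(anova_one_way(list(rep(2, 5), rep(2, 6)))[c("f", "p")],
               list(f = 0, p = 1))
  expect_error(anova_one_way(list(1, c(2, 3))), ">= 2 values")
})

test_that("paired t-test handles identical, degenerate and shifted samples", {
  a <- c(1, 2, 3, 4)
  expect_equal(paired_ttest(a, a)[c("t", "p")], list(t = 0, p = 1))
  res <- paired_ttest(a + 2, a)
  expect_equal(res$t, Inf)
  expect_equal(res$p, 0)
  expect_error(paired_ttest(a, a[1:3]), "equal length")

  set.seed(9)
  x <- rnorm(15); y <- x + rnorm(15, 0.5, 0.2)
  ref <- stats::t.test(x, y, paired = TRUE)
  got <- paired_ttest(x, y)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("paired t-test rejection rate matches the analytic power", {
  n <- 30; delta <- 0.5; reps <- 1500
  target <- stats::power.t.test(n = n, delta = delta, sd = 1,
                                sig.level = 0.05, type = "paired")$power
  set.seed(10)
  rejections <- 0
  for (r in seq_len(reps)) {
    b <- rnorm(n)
    a <- b + rnorm(n, delta, 1)
    if (paired_ttest(a, b)$p < 0.05) rejections <- rejections + 1
  }
  expect_lt(abs(rejections / reps - target), 0.04)
})

test_that("best and optimal model selection follows the comparability rule", {
  fake <- function(k, auc) {
    structure(list(feature_count = k, auc_mean = auc,
                   auc_samples = rep(auc, 3)), class = "model_evaluation")
  }
  # the published pattern: max 0.96 at 17 features, 0.93 at 8 features
  aucs <- c(0.70, 0.74, 0.78, 0.80, 0.82, 0.84, 0.88, 0.93, 0.935, 0.94,
            0.94, 0.93, 0.94, 0.95, 0.94, 0.95, 0.96, 0.955, 0.95, 0.95)
  evals <- structure(lapply(1:20, function(k) fake(k, aucs[k])),
                     class = "model_evaluation_list")
  sel <- select_best_and_optimal(evals)
  expect_equal(sel$best, 17L)
  expect_equal(sel$optimal, 8L)   # 0.93 > 0.95 * 0.96 = 0.912
  expect_equal(sel$max_auc, 0.96)

  single <- structure(list(fake(4, 0.9)), class = "model_evaluation_list")
  sel1 <- select_best_and_optimal(single)
  expect_equal(sel1$best, 4L)
  expect_equal(sel1$optimal, 4L)

  mono <- structure(lapply(1:6, function(k) fake(k, 0.5 + 0.08 * k)),
                    class = "model_evaluation_list")
  selm <- select_best_and_optimal(mono)
  expect_lte(selm$optimal, selm$best)
})

test_that("series evaluation produces 50 AUC samples per subset and sane nulls", {
  tab <- blob_table(40, seed = 11)
  series <- single_series(c("f1", "f2"), ensemble_hyperparams(60))
  ev <- evaluate_model_series(series, tab, cv_scheme(5, 10, seed = 12),
                              seed = 13)
  expect_length(ev, 1L)
  expect_length(ev[[1]]$auc_samples, 50L)
  expect_gt(ev[[1]]$auc_mean, 0.95)  # separable blobs
  expect_true(all(ev[[1]]$default$per_class_tpr >= 0 &
                    ev[[1]]$default$per_class_tpr <= 100))
  expect_true(ev[[1]]$optimal$overall >= 0 && ev[[1]]$optimal$overall <= 100)

  perm <- tab
  set.seed(14)
  perm$outcome <- sample(perm$outcome)
  evp <- evaluate_model_series(series, perm, cv_scheme(5, 10, seed = 12),
                               seed = 13)
  expect_lt(abs(evp[[1]]$auc_mean - 0.5), 0.1)
})
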