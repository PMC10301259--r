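test_that("posteriors are proper distributions and training memorizes singletons", {
  tab <- blob_table(50, seed = 1)
  fit <- train_bagged_ensemble(tab, c("f1", "f2"), ensemble_hyperparams(60),
                               seed = 2)
  post <- predict(fit, tab)
  expect_true(all(post >= 0))
  expect_lt(max(abs(rowSums(post) - 1)), 1e-9)
  expect_identical(colnames(post), c("no_fall", "L_fall", "E_fall"))

  one_each <- data.frame(f1 = c(0, 10, 20), f2 = 0,
                         outcome = factor(c("no_fall", "L_fall", "E_fall"),
                                          levels = c("no_fall", "L_fall",
                                                     "E_fall")))
  fit1 <- train_bagged_ensemble(one_each, c("f1", "f2"),
                                ensemble_hyperparams(100, min_leaf_size = 1),
                                seed = 1)
  expect_equal(as.character(predict(fit1, one_each, type = "class")),
               c("no_fall", "L_fall", "E_fall"))
})

test_that("training is seed-deterministic and rejects degenerate inputs", {
  tab <- blob_table(30, seed = 2)
  a <- train_bagged_ensemble(tab, c("f1", "f2"), seed = 5)
  b <- train_bagged_ensemble(tab, c("f1", "f2"), seed = 5)
  expect_identical(predict(a, tab), predict(b, tab))
  one_class <- tab[tab$outcome == "no_fall", ]
  expect_error(train_bagged_ensemble(one_class, c("f1", "f2")),
               "single class")
  expect_error(train_bagged_ensemble(tab, c("f1", "missing")),
               "not in table")
})

test_that("well-separated blobs are classified near-perfectly under CV", {
  tab <- blob_table(100, seed = 3)
  folds <- stratified_folds(tab, cv_scheme(5, 1, seed = 4))[[1]]
  correct <- 0
  for (f in 1:5) {
    fit <- train_bagged_ensemble(tab[folds != f, ], c("f1", "f2"),
                                 ensemble_hyperparams(100), seed = f)
    pred <- predict(fit, tab[folds == f, ], type = "class")
    correct <- correct + sum(pred == tab$outcome[folds == f])
  }
  expect_gt(correct / nrow(tab), 0.95)
})

test_that("ensemble accuracy agrees with an independent forest on the same task", {
  skip_if_not_installed("ranger")
  tab <- blob_table(80, seed = 6)
  half <- seq_len(nrow(tab)) %% 2 == 0
  fit <- train_bagged_ensemble(tab[half, ], c("f1", "f2"),
                               ensemble_hyperparams(200), seed = 1)
  acc_ours <- mean(predict(fit, tab[!half, ], type = "class") ==
                     tab$outcome[!half])
  rf <- ranger::ranger(outcome ~ f1 + f2, data = tab[half, ],
                       num.trees = 200, mtry = 2, min.node.size = 5,
                       seed = 1, num.threads = 1)
  acc_rf <- mean(stats::predict(rf, tab[!half, ],
                                num.threads = 1)$predictions ==
                   tab$outcome[!half])
  expect_lt(abs(acc_ours - acc_rf), 0.05)
})

test_that("split budget and leaf size constrain every tree", {
  tab <- blob_table(100, seed = 7)
  fit <- train_bagged_ensemble(tab, c("f1", "f2"),
                               ensemble_hyperparams(50, max_num_splits = 2),
                               seed = 1)
  expect_true(all(vapply(fit$trees, function(t) t$n_splits, 0L) <= 2L))
  stumps <- train_bagged_ensemble(tab, c("f1", "f2"),
                                  ensemble_hyperparams(50, max_num_splits = 1),
                                  seed = 1)
  expect_true(all(vapply(stumps$trees, function(t) t$n_splits, 0L) <= 1L))
})

test_that("predictor importance is a distribution concentrated on used features", {
  tab <- separable_table(n = 80, seed = 8)
  stumps <- train_bagged_ensemble(tab, c("signal", "noise"),
                                  ensemble_hyperparams(80, max_num_splits = 1),
                                  seed = 1)
  imp <- predictor_importance(stumps)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))
  # every stump splits on the separating feature
  expect_equal(unname(imp["signal"]), 1)
  expect_equal(unname(imp["noise"]), 0)
})

test_that("the informative feature ranks first in nearly all seeded runs", {
  wins <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 120
    tab <- data.frame(info = c(rnorm(n / 2, 0), rnorm(n / 2, 2.5)),
                      n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                      n4 = rnorm(n))
    tab$outcome <- factor(rep(c("no_fall", "L_fall"), each = n / 2),
                          levels = c("no_fall", "L_fall", "E_fall"))
    fit <- train_bagged_ensemble(tab, names(tab)[1:5],
                                 ensemble_hyperparams(60), seed = s)
    imp <- predictor_importance(fit)
    wins <- wins + (names(which.max(imp)) == "info")
  }
  expect_gte(wins, 19)
})

test_that("random search returns valid hyperparameters and honours the budget", {
  tab <- blob_table(60, seed = 9)
  hp1 <- tune_hyperparams(tab, c("f1", "f2"), budget = 1, seed = 3)
  expect_s3_class(hp1, "ensemble_hyperparams")
  expect_equal(hp1$min_leaf_size, 5L)
  expect_equal(nrow(attr(hp1, "search")), 1L)
  expect_identical(tune_hyperparams(tab, c("f1", "f2"), budget = 1, seed = 3),
                   tune_hyperparams(tab, c("f1", "f2"), budget = 1, seed = 3))

  hp <- tune_hyperparams(tab, c("f1", "f2"), budget = 8, seed = 4)
  expect_equal(hp$min_leaf_size, 5L)
  expect_true(hp$n_learning_cycles >= 10 && hp$n_learning_cycles <= 500)
  expect_true(hp$max_num_splits >= 1 &&
                hp$max_num_splits <= nrow(tab) - 1)
  search <- attr(hp, "search")
  expect_equal(nrow(search), 8L)
  expect_equal(search$log_loss[which.min(search$log_loss)],
               min(search$log_loss))
})

test_that("tuning does not underperform the default on separable data", {
  tab <- blob_table(60, seed = 10)
  cvacc <- function(hp) {
    folds <- stratified_folds(tab, cv_scheme(3, 1, seed = 11))[[1]]
    mean(vapply(1:3, function(f) {
      fit <- train_bagged_ensemble(tab[folds != f, ], c("f1", "f2"), hp,
                                   seed = f)
      mean(predict(fit, tab[folds == f, ], type = "class") ==
             tab$outcome[folds == f])
    }, numeric(1)))
  }
  tuned <- tune_hyperparams(tab, c("f1", "f2"), budget = 10, seed = 12)
  expect_gte(cvacc(tuned), cvacc(ensemble_hyperparams()) - 0.02)
})

test_that("backward elimination yields strictly nested subsets with a full record", {
  tab <- blob_table(60, p = 6, seed = 13)
  feats <- paste0("f", 1:6)
  series <- build_nested_models(tab, feats, hp_budget = 0, seed = 14)
  expect_length(series$subsets, 6L)
  for (k in 1:6) expect_length(series$subsets[[k]], k)
  for (k in 1:5) {
    expect_true(all(series$subsets[[k]] %in% series$subsets[[k + 1]]))
  }
  # each dropped feature appears exactly once; drops + smallest subset
  # reconstruct the full selection
  expect_equal(nrow(series$elimination), 5L)
  expect_false(anyDuplicated(series$elimination$dropped) > 0)
  expect_setequal(c(series$elimination$dropped, series$subsets[[1]]), feats)
})

test_that("a dominant feature survives to the final singleton model", {
  set.seed(15)
  n <- 120
  tab <- data.frame(dominant = c(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 4, 0.3)),
                    w1 = rnorm(n), w2 = rnorm(n), w3 = rnorm(n))
  tab$outcome <- factor(rep(c("no_fall", "L_fall"), each = n / 2),
                        levels = c("no_fall", "L_fall", "E_fall"))
  series <- build_nested_models(tab, c("dominant", "w1", "w2", "w3"),
                                hp_budget = 0, seed = 16)
  expect_identical(series$subsets[[1]], "dominant")
})
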