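#' Build the nested model series by backward feature elimination
#'
#' Starting from the ReliefF-selected subset (20 features in the study
#' setting), repeatedly trains the bagged ensemble on the current subset,
#' scores features with [predictor_importance()], and removes the feature
#' with the lowest importance until one feature remains — yielding strictly
#' nested subsets of sizes `p, p-1, ..., 1` and one trained model per size.
#' Importance ties are broken against the feature ranked lower in the input
#' (ReliefF) ordering, so runs are reproducible.
#'
#' @param table Labelled feature table.
#' @param selected Ordered character vector of selected features (best
#'   first); the study design uses 20.
#' @param hp_budget Random-search budget for [tune_hyperparams()] per
#'   subset; 0 skips tuning and uses [ensemble_hyperparams()] defaults.
#' @param seed Integer seed.
#' @return An object of class `nested_model_series` with elements `subsets`
#'   (named list, sizes as names), `models`, `hp` (per-subset
#'   hyperparameters), and `elimination` (`data.frame` recording, for each
#'   subset size, which feature was dropped and its importance).
#' @export
build_nested_models <- function(table, selected, hp_budget = 30, seed = 1) {
  selected <- as.character(selected)
  if (length(selected) < 1 || anyDuplicated(selected)) {
    stopf("selected must be a non-empty list of unique features")
  }
  miss <- setdiff(selected, names(table))
  if (length(miss)) stopf("features not in table: %s", paste(miss, collapse = ", "))
  p0 <- length(selected)
  subsets <- models <- hps <- vector("list", p0)
  elim <- data.frame(size = integer(), dropped = character(),
                     importance = numeric())
  current <- selected
  for (k in seq(p0, 1)) {
    hp <- if (hp_budget >= 1) {
      tune_hyperparams(table, current, budget = hp_budget,
                       seed = derive_seed(seed, k, 1))
    } else {
      ensemble_hyperparams()
    }
    fit <- train_bagged_ensemble(table, current, hp,
                                 seed = derive_seed(seed, k, 2))
    subsets[[k]] <- current
    models[[k]] <- fit
    hps[[k]] <- hp
    if (k > 1) {
      imp <- predictor_importance(fit)
      # lowest importance; ties drop the feature ranked lower by ReliefF
      # (i.e. later in `selected`)
      lowest <- which(imp == min(imp))
      drop_f <- current[lowest][which.max(match(current[lowest], selected))]
      elim <- rbind(elim, data.frame(size = k, dropped = drop_f,
                                     importance = unname(imp[drop_f])))
      current <- setdiff(current, drop_f)
    }
  }
  names(subsets) <- names(models) <- names(hps) <- as.character(seq_len(p0))
  structure(list(subsets = subsets, models = models, hp = hps,
                 elimination = elim, selected = selected, seed = seed),
            class = "nested_model_series")
}

#' @export
print.nested_model_series <- function(x, ...) {
  p0 <- length(x$subsets)
  cat(sprintf("Nested model series: %d models (feature counts %d ... 1)\n",
              p0, p0))
  cat("  elimination order:",
      paste(rev(x$elimination$dropped), collapse = " < "), "\n")
  invisible(x)
}
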