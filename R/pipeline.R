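#' Configuration for an end-to-end pipeline run
#'
#' Bundles every knob of the simulate/load -> rank -> select -> train ->
#' evaluate -> report chain. Either `input` (feature-table CSV path) or
#' `spec` (a [class_distribution_spec()], used to generate the table) feeds
#' the run; the default is the 40-feature synthetic cohort of
#' [default_feature_spec()].
#'
#' @param seed Integer master seed; recorded in every output artifact.
#' @param output_dir Where result files are written; `NULL` disables file
#'   output.
#' @param input Optional path to a labelled feature-table CSV.
#' @param spec Distribution spec used when `input` is `NULL`.
#' @param demographics Add synthetic age/gender/height/weight columns to the
#'   feature pool before ranking.
#' @param k_neighbors ReliefF neighbour count.
#' @param top_fraction Fraction of features kept after ranking (0.5 keeps
#'   the study's top 20 of 40).
#' @param cv A [cv_scheme()] (its seed is derived from `seed` if left at the
#'   constructor default).
#' @param hp_budget Random-search budget per feature subset.
#' @param tune_mode,cutoff_mode Passed to [evaluate_model_series()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, output_dir = NULL, input = NULL,
                       spec = default_feature_spec(), demographics = FALSE,
                       k_neighbors = 10, top_fraction = 0.5,
                       cv = cv_scheme(5, 10, seed = derive_seed(seed, 99)),
                       hp_budget = 30,
                       tune_mode = c("fast", "per_fold"),
                       cutoff_mode = c("train", "pooled")) {
  if (!is.null(input) && !file.exists(input)) {
    stopf("input file not found: %s", input)
  }
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 input = input, spec = spec,
                 demographics = isTRUE(demographics),
                 k_neighbors = k_neighbors, top_fraction = top_fraction,
                 cv = cv, hp_budget = hp_budget,
                 tune_mode = match.arg(tune_mode),
                 cutoff_mode = match.arg(cutoff_mode)),
            class = "run_config")
}

config_hash <- function(config) {
  strip <- config[setdiff(names(config), "output_dir")]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(strip, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Validate a feature-table file or data.frame
#'
#' Report-only schema check: presence of the `outcome` column, label
#' vocabulary (`no_fall`, `L_fall`, `E_fall`), uniqueness of feature names,
#' numeric feature columns, and absence of missing values. Violations carry
#' row/column coordinates.
#'
#' @param table Path to a CSV or a `data.frame`.
#' @return A `data.frame` of violations (zero rows = clean) with columns
#'   `type`, `row`, `column`, `message`, of class `table_validation`.
#' @export
validate_table <- function(table) {
  if (is.character(table)) table <- read_feature_table(table)
  v <- data.frame(type = character(), row = integer(), column = character(),
                  message = character())
  flag <- function(type, row, column, message) {
    v <<- rbind(v, data.frame(type = type, row = as.integer(row),
                              column = column, message = message))
  }
  if (anyDuplicated(names(table))) {
    for (nm in unique(names(table)[duplicated(names(table))])) {
      flag("duplicate_column", NA, nm, "duplicated column name")
    }
  }
  if (!"outcome" %in% names(table)) {
    flag("missing_column", NA, "outcome", "no 'outcome' column")
  } else {
    lab <- as.character(table$outcome)
    bad <- which(!lab %in% outcome_levels() & !is.na(lab))
    for (i in bad) {
      flag("bad_label", i, "outcome",
           sprintf("unknown outcome '%s' (expected %s)", lab[i],
                   paste(outcome_levels(), collapse = "|")))
    }
    for (i in which(is.na(lab))) flag("missing_value", i, "outcome",
                                      "missing outcome")
  }
  for (nm in setdiff(names(table), "outcome")) {
    col <- table[[nm]]
    if (!is.numeric(col)) {
      flag("non_numeric", NA, nm, "feature column is not numeric")
      next
    }
    for (i in which(!is.finite(col))) {
      flag("missing_value", i, nm, "missing or non-finite value")
    }
  }
  structure(v, class = c("table_validation", "data.frame"))
}

#' @export
print.table_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("Table validation: no violations\n")
  } else {
    cat(sprintf("Table validation: %d violation(s)\n", nrow(x)))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Run the full fall-risk modelling pipeline
#'
#' Executes the chain: load or generate the labelled feature table
#' (optionally adding demographics), rank features with ReliefF, keep the
#' top fraction, build the nested model series by backward elimination, and
#' evaluate every subset under repeated stratified CV; then compares the
#' models by one-way ANOVA on their AUC samples and selects the best and
#' optimal models. With an `output_dir`, writes the ranking, elimination
#' record, accuracy tables at both cutoffs, the per-split AUC long table,
#' per-model/class ROC coordinates and a machine-readable run manifest, all
#' stamped with the seed and config hash. Rerunning the same config
#' reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return An object of class `pipeline_run` with elements `table`,
#'   `ranking`, `selected`, `series`, `evaluations`, `anova`, `selection`,
#'   `manifest` and (if written) `files`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  table <- if (!is.null(config$input)) {
    read_feature_table(config$input)
  } else {
    generate_feature_table(config$spec, seed = derive_seed(config$seed, 1))
  }
  v <- validate_table(table)
  if (nrow(v) > 0) {
    print(v)
    stopf("input table failed schema validation (%d violation(s))", nrow(v))
  }
  if (config$demographics) {
    table <- attach_demographics(table, seed = derive_seed(config$seed, 2))
  }
  n_pool <- length(feature_columns(table))
  ranking <- relieff_rank(table, k_neighbors = config$k_neighbors)
  selected <- select_top_fraction(ranking, config$top_fraction)
  series <- build_nested_models(table, selected,
                                hp_budget = config$hp_budget,
                                seed = derive_seed(config$seed, 3))
  evals <- evaluate_model_series(series, table, scheme = config$cv,
                                 seed = derive_seed(config$seed, 4),
                                 tune_mode = config$tune_mode,
                                 hp_budget = config$hp_budget,
                                 cutoff_mode = config$cutoff_mode)
  aov_res <- anova_one_way(lapply(evals, function(e) e$auc_samples))
  selection <- select_best_and_optimal(evals)

  hash <- config_hash(config)
  manifest <- list(
    package = "tripfall",
    version = as.character(utils::packageVersion("tripfall")),
    seed = config$seed,
    config_hash = hash,
    n_rows = nrow(table),
    n_feature_pool = n_pool,
    n_selected = length(selected),
    n_models = length(series$subsets),
    n_splits_per_model = config$cv$n_folds * config$cv$n_repeats,
    cv = list(n_folds = config$cv$n_folds, n_repeats = config$cv$n_repeats,
              seed = config$cv$seed),
    hp_budget = config$hp_budget,
    tune_mode = config$tune_mode,
    cutoff_mode = config$cutoff_mode,
    demographics = config$demographics,
    selected_features = selected,
    best_model = selection$best,
    optimal_model = selection$optimal,
    max_auc = selection$max_auc,
    anova = aov_res)

  run <- structure(list(table = table, ranking = ranking,
                        selected = selected, series = series,
                        evaluations = evals, anova = aov_res,
                        selection = selection, manifest = manifest,
                        config = config),
                   class = "pipeline_run")
  if (!is.null(config$output_dir)) {
    run$files <- write_run_outputs(run, config$output_dir, hash)
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Pipeline run (seed %d): %d rows, %d-feature pool, %d selected\n",
              m$seed, m$n_rows, m$n_feature_pool, m$n_selected))
  cat(sprintf("  %d nested models x %d splits; best = %d features (AUC %.3f), optimal = %d\n",
              m$n_models, m$n_splits_per_model, m$best_model, m$max_auc,
              m$optimal_model))
  invisible(x)
}

# Accuracy table in the published layout: one row per model size, the
# feature added at that size, then overall and per-class accuracies (%).
accuracy_table <- function(run, which = c("default", "optimal")) {
  which <- match.arg(which)
  evals <- run$evaluations
  series <- run$series
  rows <- lapply(sort(vapply(evals, function(e) e$feature_count, integer(1))),
                 function(k) {
    e <- evals[[k]]
    new_feat <- if (k == 1) series$subsets[["1"]] else {
      setdiff(series$subsets[[as.character(k)]],
              series$subsets[[as.character(k - 1)]])
    }
    blk <- e[[which]]
    data.frame(
      feature_number = k,
      new_feature = new_feat,
      overall = round(blk$overall, 1),
      no_fall = round(unname(blk$per_class_tpr["no_fall"]), 1),
      E_fall = round(unname(blk$per_class_tpr["E_fall"]), 1),
      L_fall = round(unname(blk$per_class_tpr["L_fall"]), 1))
  })
  do.call(rbind, rows)
}

write_run_outputs <- function(run, output_dir, hash) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(seed = run$config$seed, config = hash)
  out <- function(name) file.path(output_dir, name)
  stamp_csv <- function(df, name) {
    write_feature_table(df, out(name), meta = meta)
    out(name)
  }
  files <- c(
    table = stamp_csv(run$table, "feature_table.csv"),
    ranking = stamp_csv(as.data.frame(run$ranking), "relieff_ranking.csv"),
    elimination = stamp_csv(run$series$elimination, "elimination_record.csv"),
    accuracy_default = stamp_csv(accuracy_table(run, "default"),
                                 "accuracy_default_cutoff.csv"),
    accuracy_optimal = stamp_csv(accuracy_table(run, "optimal"),
                                 "accuracy_optimal_cutoff.csv"),
    auc = stamp_csv(do.call(rbind, lapply(run$evaluations, function(e) {
      data.frame(feature_count = e$feature_count,
                 split = seq_along(e$auc_samples),
                 macro_auc = e$auc_samples)
    })), "auc_samples.csv"))
  manifest_path <- out("manifest.json")
  writeLines(jsonlite::toJSON(run$manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), manifest_path)
  c(files, manifest = manifest_path)
}
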