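#' Read and write labelled feature tables
#'
#' Feature tables are plain CSV with one header row, one numeric column per
#' feature (names kept verbatim, spaces allowed) and an `outcome` column with
#' values `no_fall`, `L_fall` or `E_fall`. Lines starting with `#` are
#' metadata comments (seed, config hash) and are skipped on read.
#'
#' @param path File path.
#' @param table Feature table (`data.frame`).
#' @param meta Optional named character vector written as `# key=value`
#'   comment lines before the header.
#' @return `read_feature_table()` returns a `data.frame` with `outcome` as a
#'   factor; `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  if ("outcome" %in% names(out)) {
    out$outcome <- factor(out$outcome, levels = outcome_levels())
  }
  out
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(table, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  }
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read and write marker trajectories (long-format CSV)
#'
#' Columns: `frame` (1-based), `time_s`, `marker`, `x` (anterior, m),
#' `y` (vertical up, m), `z` (mediolateral, m).
#'
#' @param traj A [marker_trajectory_set()].
#' @param path File path.
#' @param sampling_rate Required on read if the file has fewer than two
#'   frames; otherwise inferred from `time_s`.
#' @return `read_marker_trajectories()` returns a [marker_trajectory_set()].
#' @export
write_marker_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "marker_trajectory_set"))
  pos <- traj$positions
  nf <- dim(pos)[1]
  markers <- dimnames(pos)[[2]]
  long <- do.call(rbind, lapply(markers, function(m) {
    data.frame(frame = seq_len(nf),
               time_s = (seq_len(nf) - 1) / traj$sampling_rate,
               marker = m,
               x = pos[, m, "x"], y = pos[, m, "y"], z = pos[, m, "z"])
  }))
  long <- long[order(long$frame, match(long$marker, markers)), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_trajectories
#' @export
read_marker_trajectories <- function(path, sampling_rate = NULL) {
  long <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  need <- c("frame", "time_s", "marker", "x", "y", "z")
  if (!all(need %in% names(long))) {
    stopf("marker CSV must have columns: %s", paste(need, collapse = ", "))
  }
  markers <- unique(long$marker)
  frames <- sort(unique(long$frame))
  nf <- length(frames)
  if (is.null(sampling_rate)) {
    tt <- tapply(long$time_s, long$frame, function(v) v[1])
    dt <- diff(as.numeric(tt))
    if (length(dt) < 1) stopf("need sampling_rate for a single-frame record")
    sampling_rate <- 1 / stats::median(dt)
  }
  pos <- array(NA_real_, dim = c(nf, length(markers), 3),
               dimnames = list(NULL, markers, c("x", "y", "z")))
  fr <- match(long$frame, frames)
  mk <- match(long$marker, markers)
  for (k in seq_along(c("x", "y", "z"))) {
    pos[cbind(fr, mk, k)] <- long[[c("x", "y", "z")[k]]]
  }
  marker_trajectory_set(pos, sampling_rate = sampling_rate)
}

#' Serialize distribution and trial specifications as YAML
#'
#' Field names mirror the corresponding constructor arguments, so a file can
#' be round-tripped with [class_distribution_spec()] / [gait_trial_spec()].
#'
#' @param spec The object to serialize.
#' @param path File path.
#' @return Read functions return the reconstructed object.
#' @export
write_class_spec <- function(spec, path) {
  stopifnot(inherits(spec, "class_distribution_spec"))
  obj <- list(
    class_names = spec$class_names,
    class_counts = as.integer(spec$class_counts),
    feature_names = spec$feature_names,
    means = apply(spec$means, 1, as.list, simplify = FALSE),
    sds = apply(spec$sds, 1, as.list, simplify = FALSE),
    separation_boost = spec$separation_boost)
  if (!is.null(spec$correlation)) {
    obj$correlation <- lapply(spec$correlation, function(m) {
      apply(unname(m), 1, as.numeric, simplify = FALSE)
    })
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_class_spec
#' @export
read_class_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  feats <- as.character(obj$feature_names)
  to_mat <- function(lst) {
    do.call(rbind, lapply(obj$class_names, function(cl) {
      unlist(lst[[cl]])[feats]
    }))
  }
  correlation <- NULL
  if (!is.null(obj$correlation)) {
    correlation <- lapply(obj$correlation, function(rows) {
      do.call(rbind, lapply(rows, as.numeric))
    })
  }
  class_distribution_spec(
    class_names = obj$class_names,
    class_counts = obj$class_counts,
    feature_names = feats,
    means = to_mat(obj$means), sds = to_mat(obj$sds),
    correlation = correlation,
    separation_boost = obj$separation_boost %||% 1)
}

#' @rdname write_class_spec
#' @export
write_trial_spec <- function(spec, path) {
  stopifnot(inherits(spec, "gait_trial_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_class_spec
#' @export
read_trial_spec <- function(path) {
  do.call(gait_trial_spec, yaml::read_yaml(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
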