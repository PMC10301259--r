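# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds below 2^31, spread out to avoid stream overlap.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 48271 + as.numeric(p) + 1) %% 2147483647
  as.integer(h)
}

outcome_levels <- function() c("no_fall", "L_fall", "E_fall")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && abs(x - round(x)) < 1e-8

feature_columns <- function(table) {
  setdiff(names(table), "outcome")
}

outcome_of <- function(table) {
  if (!"outcome" %in% names(table)) stopf("table has no 'outcome' column")
  factor(table$outcome, levels = outcome_levels())
}
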