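test_that("packaged study spec reproduces the published class summaries", {
  spec <- table1_spec()
  expect_equal(spec$means["no_fall", "COM velocity at LO"], 1.03)
  expect_equal(spec$sds["no_fall", "COM velocity at LO"], 0.19)
  expect_equal(spec$means["E_fall", "Toe clearance"], 0.16)
  expect_equal(spec$sds["E_fall", "Toe clearance"], 0.02)
  expect_equal(spec$means["no_fall", "Max knee flexion in swing phase"], 119.18)
  expect_equal(unname(spec$class_counts),  c(192L, 84L, 22L))
  expect_equal(sum(spec$class_counts), 298L)
  expect_equal(length(spec$feature_names), 20L)
})

test_that("the 40-feature pool extends the study spec with uninformative features", {
  spec <- default_feature_spec()
  expect_setequal(spec$feature_names, feature_names_full())
  expect_equal(length(spec$feature_names), 40L)
  # the lower-ranked features are class-independent
  lower <- setdiff(spec$feature_names, table1_spec()$feature_names)
  for (f in lower) {
    expect_equal(length(unique(spec$means[, f])), 1L)
    expect_equal(length(unique(spec$sds[, f])), 1L)
  }
})

test_that("generated tables have exact class counts and are seed-deterministic", {
  tab <- generate_feature_table(table1_spec(), seed = 1)
  expect_equal(nrow(tab), 298L)
  expect_equal(as.vector(table(tab$outcome)), c(192L, 84L, 22L))
  expect_identical(tab, generate_feature_table(table1_spec(), seed = 1))
  expect_false(identical(tab, generate_feature_table(table1_spec(), seed = 2)))
})

test_that("zero-variance spec yields exactly the configured means", {
  spec <- table1_spec()
  spec$sds[] <- 0
  tab <- generate_feature_table(spec, seed = 7)
  no_fall <- tab[tab$outcome == "no_fall", ]
  expect_true(all(no_fall[["COM velocity at LO"]] == 1.03))
  expect_true(all(no_fall[["Toe clearance"]] == 0.16))
})

test_that("large-sample moments match the configured marginals", {
  spec <- table1_spec()
  n <- 1e4
  spec$class_counts[] <- c(n, n, n)
  tab <- generate_feature_table(spec, seed = 3)
  for (cl in spec$class_names) {
    block <- tab[tab$outcome == cl, spec$feature_names]
    mu_hat <- colMeans(block)
    sd_hat <- apply(block, 2, sd)
    expect_true(all(abs(mu_hat - spec$means[cl, ]) <=
                      4 * spec$sds[cl, ] / sqrt(n)))
    expect_true(all(abs(sd_hat - spec$sds[cl, ]) <= 0.05 * spec$sds[cl, ]))
  }
})

test_that("law-of-large-numbers check at 1e5 rows per class", {
  spec <- table1_spec()
  spec$class_counts[] <- c(1e5, 1, 1)
  tab <- generate_feature_table(spec, seed = 1)
  m <- mean(tab[tab$outcome == "no_fall", "Max knee flexion in swing phase"])
  expect_lt(abs(m - 119.18), 0.1)
})

test_that("a user-supplied correlation structure is honoured and checked", {
  spec <- table1_spec()
  p <- length(spec$feature_names)
  R <- diag(p)
  R[1, 2] <- R[2, 1] <- 0.8
  spec$correlation <- stats::setNames(rep(list(R), 3), spec$class_names)
  spec$class_counts[] <- c(5000, 1, 1)
  tab <- generate_feature_table(spec, seed = 5)
  block <- tab[tab$outcome == "no_fall", ]
  r_hat <- cor(block[[spec$feature_names[1]]], block[[spec$feature_names[2]]])
  expect_lt(abs(r_hat - 0.8), 0.05)

  R_bad <- R
  R_bad[1, 2] <- R_bad[2, 1] <- 1.5  # not PSD
  spec$correlation[["L_fall"]] <- R_bad
  expect_error(generate_feature_table(spec, seed = 1),
               "L_fall.*positive semi-definite")
})

test_that("separation boost scales between-class mean differences", {
  spec <- table1_spec(separation_boost = 3)
  spec$sds[] <- 0
  tab <- generate_feature_table(spec, seed = 1)
  base <- table1_spec()
  f <- "COM velocity at LO"
  grand <- mean(base$means[, f])
  for (cl in base$class_names) {
    got <- unique(tab[tab$outcome == cl, f])
    expect_equal(got, grand + 3 * (base$means[cl, f] - grand))
  }
})

test_that("demographics attach independently of class with the cohort moments", {
  tab <- generate_feature_table(table1_spec(), seed = 1)
  out <- attach_demographics(tab, seed = 2)
  expect_equal(nrow(out), 298L)
  expect_true(all(c("age", "gender", "height", "weight") %in% names(out)))
  expect_equal(ncol(out), ncol(tab) + 4L)
  expect_error(attach_demographics(out, seed = 3), "already has demographic")

  big <- tab[rep(seq_len(nrow(tab)), 40), ]  # ~12k rows
  bigd <- attach_demographics(big, seed = 4)
  expect_lt(abs(mean(bigd$age) - 69.6), 0.5)
  expect_lt(abs(mean(bigd$gender) - 128 / 298), 0.03)
  expect_lt(abs(mean(bigd$height) - 1.67), 0.01)
})

test_that("feature tables and specs round-trip through CSV and YAML", {
  tab <- generate_feature_table(table1_spec(), seed = 1)
  csv <- tempfile(fileext = ".csv")
  write_feature_table(tab, csv, meta = c(seed = 1))
  back <- read_feature_table(csv)
  expect_equal(names(back), names(tab))
  expect_equal(as.character(back$outcome), as.character(tab$outcome))
  expect_equal(back[["COM velocity at LO"]], tab[["COM velocity at LO"]],
               tolerance = 1e-12)

  yml <- tempfile(fileext = ".yaml")
  write_class_spec(table1_spec(), yml)
  spec2 <- read_class_spec(yml)
  expect_equal(spec2$means, table1_spec()$means)
  expect_equal(spec2$class_counts, table1_spec()$class_counts)
})
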