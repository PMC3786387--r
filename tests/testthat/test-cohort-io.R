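test_that("schema partitions the 18 outcomes into the five domains", {
  sch <- domain_schema()
  expect_s3_class(sch, "domain_schema")
  expect_equal(nrow(sch), 18L)
  expect_equal(attr(sch, "domains"), c("D1", "D2", "D3", "D4", "D5"))
  counts <- table(sch$domain)
  expect_equal(as.integer(counts[c("D1", "D2", "D3", "D4", "D5")]),
               c(4L, 4L, 7L, 2L, 1L))
  # inverted: the four Stroop measures and the two forgetting scores
  expect_setequal(sch$outcome[sch$invert],
                  c("stroop_dots_time", "stroop_words_time",
                    "stroop_colors_time", "stroop_interference_ratio",
                    "ravlt_short_delay_forgetting",
                    "ravlt_long_delay_forgetting"))
})

test_that("cohort CSV round-trips and coerces bad numeric cells to missing", {
  df <- tiny_cohort_df()
  path <- write_tiny_cohort_csv(df)
  co <- load_cohort(path)
  expect_s3_class(co, "cohort_table")
  expect_equal(nrow(co), 3L)
  expect_equal(co$s100b, df$s100b)

  # full numeric round trip through write_cohort
  path2 <- tempfile(fileext = ".csv")
  write_cohort(co, path2)
  co2 <- load_cohort(path2)
  for (col in setdiff(names(df), c("participant_id", "sex")))
    expect_equal(co2[[col]], co[[col]], tolerance = 1e-12)

  # an unparseable score cell becomes missing; the row is retained
  df$digit_symbol_coding[2] <- "n/a"
  co3 <- suppressMessages(load_cohort(write_tiny_cohort_csv(df)))
  expect_equal(nrow(co3), 3L)
  expect_true(is.na(co3$digit_symbol_coding[2]))
  expect_equal(attr(co3, "n_unparseable"), 1L)
})

test_that("missing mandatory columns are reported by name", {
  df <- tiny_cohort_df()
  df$s100b <- NULL
  expect_error(load_cohort(write_tiny_cohort_csv(df)), "s100b")
})

test_that("exclusion rules drop low/missing MMSE and flagged rows", {
  df <- tiny_cohort_df()[c(1, 1, 1, 2, 3), ]
  df$participant_id <- paste0("P", 1:5)
  df$mmse <- c(29, 23, 24, 20, NA)
  co <- as.data.frame(df)
  class(co) <- c("cohort_table", "data.frame")
  out <- apply_exclusions(co)
  log <- attr(out, "exclusion_log")
  expect_equal(nrow(out), 2L)                       # 29 and boundary 24 kept
  expect_true(all(out$mmse >= 24))
  expect_equal(log$mmse_below_cutoff, 2L)
  expect_equal(log$mmse_missing, 1L)

  # 5-row cohort with a single mmse = 20 exclusion
  df2 <- tiny_cohort_df()[c(1, 2, 3, 1, 2), ]
  df2$mmse <- c(28, 20, 30, 27, 25)
  co2 <- as.data.frame(df2); class(co2) <- c("cohort_table", "data.frame")
  out2 <- apply_exclusions(co2)
  expect_equal(nrow(out2), 4L)
  expect_equal(attr(out2, "exclusion_log")$mmse_below_cutoff, 1L)

  # pre-coded clinical flags are honoured
  co2$renal_impairment <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  out3 <- apply_exclusions(co2)
  expect_equal(nrow(out3), 3L)
  expect_equal(attr(out3, "exclusion_log")$renal_impairment, 1L)

  co2$mmse <- rep(10, 5)
  expect_error(apply_exclusions(co2), "all participants excluded")

  # exclusion log exports as JSON
  p <- tempfile(fileext = ".json")
  write_exclusion_log(out2, p)
  expect_equal(jsonlite::read_json(p)$mmse_below_cutoff, 1L)
})

test_that("exclusions are monotone: extra rows never evict retained rows", {
  set.seed(3)
  base <- tiny_cohort_df()[sample(1:3, 20, replace = TRUE), ]
  base$participant_id <- paste0("P", 1:20)
  base$mmse <- sample(c(20:30, NA), 20, replace = TRUE)
  co <- as.data.frame(base); class(co) <- c("cohort_table", "data.frame")
  kept_small <- apply_exclusions(co[1:12, ])$participant_id
  kept_big <- apply_exclusions(co)$participant_id
  expect_true(all(kept_small %in% kept_big))
})

test_that("score inversion flips exactly the lower-is-better columns once", {
  df <- tiny_cohort_df()
  df$stroop_colors_time <- c(29.9, 35.1, 20.4)
  co <- as.data.frame(df); class(co) <- c("cohort_table", "data.frame")
  inv <- invert_scores(co)
  expect_equal(inv$stroop_colors_time[1], -29.9)
  expect_equal(inv$digit_symbol_coding, df$digit_symbol_coding)  # untouched
  expect_warning(inv2 <- invert_scores(inv), "already inverted")
  expect_equal(inv2$stroop_colors_time, inv$stroop_colors_time)
})

test_that("standardization uses the n-1 denominator and keeps missing cells", {
  expect_equal(standardize_vector(c(1, 2, 3))$values, c(-1, 0, 1))
  st <- standardize_vector(c(1, NA, 3))
  expect_equal(st$values, c(-1 / sqrt(2), NA, 1 / sqrt(2)))
  expect_error(standardize_vector(c(5, 5, 5), "flat"), "flat")
  # idempotent on complete columns
  v <- rnorm(50, 7, 3)
  once <- standardize_vector(v)$values
  expect_equal(standardize_vector(once)$values, once, tolerance = 1e-12)
})

test_that("analysis matrix is standardized, covariate-aware and order-invariant", {
  g <- generate_cohort(generator_config(n = 60, seed = 8))
  co <- g$cohort
  am0 <- build_analysis_matrix(co)
  expect_equal(ncol(am0$C), 0L)
  am2 <- build_analysis_matrix(co, covariates = c("age", "sex"))
  expect_equal(colnames(am2$C), c("age", "sex"))
  expect_equal(unname(colMeans(am2$C)), c(0, 0), tolerance = 1e-10)

  expect_equal(unname(colMeans(am0$Y, na.rm = TRUE)), rep(0, 18),
               tolerance = 1e-10)
  expect_equal(unname(apply(am0$Y, 2, sd, na.rm = TRUE)), rep(1, 18),
               tolerance = 1e-10)
  # inversion recorded in the scaling record
  rec <- am0$scaling_record
  expect_equal(sum(rec$inverted), 6L)

  # row-order invariance
  perm <- sample(nrow(co))
  co_perm <- as.data.frame(co)[perm, ]
  class(co_perm) <- c("cohort_table", "data.frame")
  amp <- build_analysis_matrix(co_perm)
  expect_equal(amp$Y, am0$Y[perm, ], tolerance = 1e-12)
  expect_equal(amp$x, am0$x[perm], tolerance = 1e-12)
})
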