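covariate_model_sets <- function() {
  list(none = character(), age_sex = c("age", "sex"),
       age_sex_nart = c("age", "sex", "nart"))
}

# minimal one-outcome schema used by the simple covariate regressions
single_outcome_schema <- function(name = "y") {
  out <- data.frame(outcome = name, domain = "D1", invert = FALSE,
                    domain_label = "single", stringsAsFactors = FALSE)
  attr(out, "domains") <- "D1"
  class(out) <- c("domain_schema", "data.frame")
  out
}

#' Robust Bayesian regression of S100B on a single covariate
#'
#' Fits a simple robust regression (Student-t errors, same prior family and
#' sampler as the nested model) of standardized S100B on the standardized
#' covariate, then back-transforms the slope to natural units (ng/mL per
#' year for age, ng/mL per NART error).  For sex the result is reported as
#' the female-minus-male contrast in ng/mL (sex is coded F = 0, M = 1
#' internally, so the contrast is the negated per-unit slope).
#'
#' @param cohort A `cohort_table` (exclusions applied or not; rows with a
#'   missing covariate or S100B are dropped for this fit).
#' @param covariate One of `"age"`, `"sex"`, `"nart"`.
#' @param config An [mcmc_config()].
#' @return A list with `covariate`, `slope` (natural units), `hdi95`,
#'   `hdi80`, `excludes_zero`, `ess`, `psrf` and the `posterior_samples`.
#' @export
covariate_regression <- function(cohort, covariate = c("age", "sex", "nart"),
                                 config = mcmc_config(preset = "test")) {
  covariate <- match.arg(covariate)
  raw <- switch(covariate,
    age = cohort$age,
    sex = ifelse(cohort$sex == "M", 1, 0),
    nart = cohort$nart_errors)
  if (is.null(raw)) stop("covariate '", covariate, "' not present in cohort")
  ok <- !is.na(raw) & !is.na(cohort$s100b)
  y <- cohort$s100b[ok]; v <- raw[ok]
  if (stats::sd(v) == 0) stop("covariate '", covariate, "' has zero variance")

  ys <- standardize_vector(y, "s100b")
  vs <- standardize_vector(v, covariate)
  schema <- single_outcome_schema("s100b")
  data <- structure(list(
    x = vs$values, Y = matrix(ys$values, ncol = 1,
                              dimnames = list(NULL, "s100b")),
    C = matrix(numeric(0), length(y), 0), schema = schema,
    covariates = character(),
    scaling_record = data.frame(
      column = c("s100b", covariate),
      center = c(ys$center, vs$center),
      scale = c(ys$scale, vs$scale), inverted = FALSE),
    n = length(y)), class = "analysis_matrix")

  model <- model_spec(schema = schema, hierarchical = FALSE)
  post <- run_mcmc(model, data, config)

  # natural-unit slope: slope_std * sd_y / sd_x; F-M contrast negates M-F
  fac <- ys$scale / vs$scale * (if (covariate == "sex") -1 else 1)
  sl <- as.vector(derived_draws(post, "beta")) * fac
  h95 <- sort(unname(hdi(sl, 0.95))); h80 <- sort(unname(hdi(sl, 0.80)))
  smry <- summarize_posterior(post, "beta")
  list(covariate = covariate, slope = mean(sl),
       hdi95 = h95, hdi80 = h80,
       excludes_zero = h95[1] > 0 || h95[2] < 0,
       ess = smry$ess, psrf = smry$psrf, posterior = post)
}

#' Fit all covariate variants of the nested model and build reports
#'
#' Runs the nested-domain model three times (no covariates; age + sex;
#' age + sex + NART), summarizes the overall, domain-level and
#' outcome-level standardized slopes, and fits the three standalone
#' S100B-vs-covariate robust regressions.
#'
#' @param cohort A `cohort_table`; exclusion rules are applied if they have
#'   not been already.
#' @param config An [mcmc_config()]; fit `m` runs on master seed
#'   `config$seed + 100 * (m - 1)` and each covariate regression on
#'   `config$seed + 1000 + its index`.
#' @param covariate_models Subset of `c("none", "age_sex", "age_sex_nart")`.
#' @return A list with `slope_report` (a data frame with one row per slope
#'   per covariate model) and `covariate_report` (one row per covariate).
#' @export
run_full_analysis <- function(cohort, config = mcmc_config(preset = "test"),
                              covariate_models = c("none", "age_sex",
                                                   "age_sex_nart")) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(attr(cohort, "exclusion_log")))
    cohort <- apply_exclusions(cohort)
  schema <- domain_schema()
  sets <- covariate_model_sets()[covariate_models]
  dom_labels <- attr(schema, "domains")

  slope_rows <- list()
  for (m in seq_along(sets)) {
    cvs <- sets[[m]]
    am <- build_analysis_matrix(cohort, schema, covariates = cvs)
    model <- model_spec(schema = schema, covariates = cvs)
    cfg <- config; cfg$seed <- as.integer(config$seed + 100L * (m - 1L))
    post <- run_mcmc(model, am, cfg)
    pars <- c("beta", paste0("domain[", seq_along(dom_labels), "]"),
              paste0("theta[", seq_len(nrow(schema)), "]"))
    sm <- summarize_posterior(post, pars)
    sm$level <- c("overall", rep("domain", length(dom_labels)),
                  rep("outcome", nrow(schema)))
    sm$name <- c("overall", dom_labels, schema$outcome)
    sm$covariate_model <- names(sets)[m]
    slope_rows[[m]] <- sm
  }
  slope_report <- do.call(rbind, slope_rows)
  slope_report <- slope_report[, c("level", "name", "covariate_model",
                                   "mean", "sd", "hdi80_lower", "hdi80_upper",
                                   "hdi95_lower", "hdi95_upper",
                                   "ess", "psrf")]
  rownames(slope_report) <- NULL
  class(slope_report) <- c("slope_report", "data.frame")

  cov_rows <- lapply(seq_along(c("age", "sex", "nart")), function(i) {
    cv <- c("age", "sex", "nart")[i]
    cfg <- config; cfg$seed <- as.integer(config$seed + 1000L + i)
    r <- covariate_regression(cohort, cv, cfg)
    data.frame(covariate = cv, slope = r$slope,
               hdi95_lower = r$hdi95[1], hdi95_upper = r$hdi95[2],
               excludes_zero = r$excludes_zero,
               units = switch(cv, age = "ng/mL per year",
                              sex = "ng/mL (F-M contrast)",
                              nart = "ng/mL per error"),
               stringsAsFactors = FALSE)
  })
  covariate_report <- do.call(rbind, cov_rows)
  class(covariate_report) <- c("covariate_report", "data.frame")

  list(slope_report = slope_report, covariate_report = covariate_report)
}

#' Export slope and covariate reports
#'
#' Writes each report as TSV and JSON (four files):
#' `slope_report.tsv/.json`, `covariate_report.tsv/.json`.
#'
#' @param reports The list returned by [run_full_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
export_reports <- function(reports, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in c("slope_report", "covariate_report")) {
    df <- as.data.frame(reports[[nm]])
    tsv <- file.path(out_dir, paste0(nm, ".tsv"))
    num <- vapply(df, is.numeric, TRUE)
    out <- df
    out[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    utils::write.table(out, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
    json <- file.path(out_dir, paste0(nm, ".json"))
    jsonlite::write_json(df, json, digits = NA, pretty = TRUE)
    paths <- c(paths, tsv, json)
  }
  invisible(paths)
}

#' Read back an exported slope report
#'
#' @param path A `slope_report.tsv` written by [export_reports()].
#' @return A `slope_report` data frame.
#' @export
read_slope_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("slope_report", "data.frame")
  df
}
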