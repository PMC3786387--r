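#' Read a participant-level cohort table from CSV
#'
#' Expects a UTF-8 CSV with a header row.  Recognised columns are
#' `participant_id`, `s100b` (ng/mL), `age` (years), `sex` (`F`/`M`),
#' `nart_errors`, `mmse`, the 18 outcome columns named as in
#' [domain_schema()], and optional pre-coded logical exclusion columns
#' (e.g. `renal_impairment`, `liver_dysfunction`).  Empty cells, `NA`, and
#' unparseable numeric cells become missing values; the number of coerced
#' cells is recorded in the `n_unparseable` attribute.
#'
#' @param path Path to the CSV file.
#' @param schema A [domain_schema()] naming the outcome columns.
#' @return A `cohort_table`: a data frame with typed columns and attributes
#'   `n_unparseable` and `scores_inverted` (initially `FALSE`).
#' @seealso [write_cohort()], [apply_exclusions()], [build_analysis_matrix()]
#' @export
load_cohort <- function(path, schema = domain_schema()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE,
                         na.strings = c("", "NA"))
  for (col in c("s100b", "mmse")) {
    if (!col %in% names(raw))
      stop("cohort file is missing mandatory column '", col, "'")
  }
  numeric_cols <- intersect(
    c("s100b", "age", "nart_errors", "mmse", outcome_names(schema)),
    names(raw))
  n_bad <- 0L
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    n_bad <- n_bad + sum(is.na(v) & !is.na(raw[[col]]))
    raw[[col]] <- v
  }
  if (n_bad > 0L)
    message(n_bad, " unparseable numeric cell(s) treated as missing")
  if ("sex" %in% names(raw)) {
    sx <- toupper(trimws(raw$sex))
    bad <- !is.na(sx) & !sx %in% c("F", "M")
    if (any(bad)) stop("sex column must contain only 'F' or 'M'")
    raw$sex <- sx
  }
  # optional logical exclusion flags arrive as "TRUE"/"FALSE"/"1"/"0"
  for (col in intersect(exclusion_flag_columns(), names(raw))) {
    raw[[col]] <- as.logical(raw[[col]]) | raw[[col]] %in% "1"
  }
  as_cohort_table(raw, n_unparseable = n_bad)
}

as_cohort_table <- function(df, n_unparseable = 0L, inverted = FALSE) {
  if (nrow(df) < 1L) stop("cohort must contain at least one row")
  if (any(!is.na(df$s100b) & df$s100b <= 0))
    stop("s100b must be positive where present")
  if (any(!is.na(df$mmse) & (df$mmse < 0 | df$mmse > 30)))
    stop("mmse must lie in [0, 30]")
  attr(df, "n_unparseable") <- n_unparseable
  attr(df, "scores_inverted") <- inverted
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", nrow(x), "participants,", ncol(x), "columns\n")
  if (isTRUE(attr(x, "scores_inverted")))
    cat("  (lower-is-better scores have been sign-inverted)\n")
  NextMethod()
}

#' Write a cohort table to CSV
#'
#' Inverse of [load_cohort()]: numeric content round-trips exactly (values
#' are written with full precision) and missing cells are written as `NA`.
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE, na = "NA")
  invisible(path)
}

exclusion_flag_columns <- function() c("renal_impairment", "liver_dysfunction")

#' Apply the cohort exclusion rules
#'
#' Removes participants with MMSE below 24 or missing MMSE, and participants
#' flagged `TRUE` on any pre-coded clinical exclusion column present in the
#' table (`renal_impairment`, `liver_dysfunction`).  The per-rule removal
#' counts are attached as the `exclusion_log` attribute and can be exported
#' with [write_exclusion_log()].
#'
#' @param cohort A `cohort_table`.
#' @param mmse_cutoff Minimum retained MMSE score (default 24, i.e. scores
#'   below 24 are excluded).
#' @return The filtered `cohort_table` with an `exclusion_log` attribute.
#' @export
apply_exclusions <- function(cohort, mmse_cutoff = 24) {
  stopifnot(inherits(cohort, "cohort_table"))
  log <- list(n_input = nrow(cohort))
  keep <- rep(TRUE, nrow(cohort))

  drop_mmse_missing <- is.na(cohort$mmse)
  drop_mmse <- !drop_mmse_missing & cohort$mmse < mmse_cutoff
  log$mmse_missing <- sum(drop_mmse_missing & keep)
  keep <- keep & !drop_mmse_missing
  log$mmse_below_cutoff <- sum(drop_mmse & keep)
  keep <- keep & !drop_mmse

  for (col in intersect(exclusion_flag_columns(), names(cohort))) {
    flag <- !is.na(cohort[[col]]) & cohort[[col]]
    log[[col]] <- sum(flag & keep)
    keep <- keep & !flag
  }
  log$n_retained <- sum(keep)
  if (!any(keep)) stop("all participants excluded")
  out <- cohort[keep, , drop = FALSE]
  out <- as_cohort_table(as.data.frame(out),
                         n_unparseable = attr(cohort, "n_unparseable"),
                         inverted = attr(cohort, "scores_inverted"))
  attr(out, "exclusion_log") <- log
  out
}

#' Export an exclusion log as JSON
#'
#' @param cohort A cohort returned by [apply_exclusions()].
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(cohort, path) {
  log <- attr(cohort, "exclusion_log")
  if (is.null(log)) stop("cohort carries no exclusion log; run apply_exclusions() first")
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Sign-invert the lower-is-better outcome scores
#'
#' Negates every outcome column whose schema `invert` flag is set (Stroop
#' times and ratio, RAVLT forgetting scores) so that larger values always
#' mean better performance.  Because standardization follows, sign negation
#' is equivalent to any other affine order-reversing transform.  A second
#' application is refused (warning + no-op) via the `scores_inverted` flag.
#'
#' @param cohort A `cohort_table`.
#' @param schema A [domain_schema()].
#' @return The cohort with inverted columns and `scores_inverted = TRUE`.
#' @export
invert_scores <- function(cohort, schema = domain_schema()) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (isTRUE(attr(cohort, "scores_inverted"))) {
    warning("scores are already inverted; returning cohort unchanged")
    return(cohort)
  }
  for (col in intersect(schema$outcome[schema$invert], names(cohort))) {
    cohort[[col]] <- -cohort[[col]]
  }
  attr(cohort, "scores_inverted") <- TRUE
  cohort
}

#' Standardize a numeric vector to mean 0, SD 1
#'
#' Uses the sample (n-1) standard deviation over non-missing entries;
#' missing entries stay missing.
#'
#' @param values Numeric vector, possibly with `NA`.
#' @param name Column name used in error messages.
#' @return A list with `values` (standardized vector), `center` and `scale`.
#' @examples
#' standardize_vector(c(1, 2, 3))$values
#' @export
standardize_vector <- function(values, name = "column") {
  ok <- !is.na(values)
  if (sum(ok) < 2L)
    stop("column '", name, "' needs at least 2 non-missing values")
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  if (!is.finite(s) || s == 0)
    stop("column '", name, "' has zero variance")
  list(values = (values - m) / s, center = m, scale = s)
}

#' Build the standardized analysis matrix
#'
#' Applies score inversion (if not already applied) followed by column-wise
#' standardization to produce the inputs the nested model consumes: the
#' standardized biomarker vector `x`, the n x 18 standardized outcome matrix
#' `Y` (missing cells allowed), and the standardized covariate matrix `C`.
#' Sex is coded F = 0, M = 1 before standardization, so a positive
#' standardized coefficient points in the F-to-M direction.
#'
#' @param cohort A `cohort_table` (exclusions applied).
#' @param schema A [domain_schema()].
#' @param covariates Character subset of `c("age", "sex", "nart")`.
#' @return An `analysis_matrix`: list with `x`, `Y`, `C`, `schema`, and a
#'   `scaling_record` data frame (column, center, scale, inverted) used for
#'   back-transformation to natural units.
#' @export
build_analysis_matrix <- function(cohort, schema = domain_schema(),
                                  covariates = character()) {
  validate_schema(schema)
  stopifnot(all(covariates %in% c("age", "sex", "nart")))
  cohort <- invert_scores_quiet(cohort, schema)
  rec <- list()

  sx <- standardize_vector(cohort$s100b, "s100b")
  rec[["s100b"]] <- c(center = sx$center, scale = sx$scale)

  miss <- setdiff(outcome_names(schema), names(cohort))
  if (length(miss))
    stop("cohort is missing outcome column(s): ", paste(miss, collapse = ", "))
  Y <- matrix(NA_real_, nrow(cohort), nrow(schema),
              dimnames = list(NULL, schema$outcome))
  for (col in schema$outcome) {
    st <- standardize_vector(cohort[[col]], col)
    Y[, col] <- st$values
    rec[[col]] <- c(center = st$center, scale = st$scale)
  }

  C <- matrix(numeric(0), nrow(cohort), 0)
  for (cv in covariates) {
    raw <- switch(cv,
      age  = cohort$age,
      sex  = ifelse(cohort$sex == "M", 1, 0),
      nart = cohort$nart_errors)
    if (is.null(raw)) stop("covariate '", cv, "' not present in cohort")
    st <- standardize_vector(raw, cv)
    C <- cbind(C, st$values)
    rec[[cv]] <- c(center = st$center, scale = st$scale)
  }
  if (length(covariates)) colnames(C) <- covariates

  scaling_record <- data.frame(
    column = names(rec),
    center = vapply(rec, `[[`, 0, "center"),
    scale  = vapply(rec, `[[`, 0, "scale"),
    inverted = names(rec) %in% schema$outcome[schema$invert],
    row.names = NULL)

  structure(
    list(x = sx$values, Y = Y, C = C, schema = schema,
         covariates = covariates, scaling_record = scaling_record,
         n = nrow(cohort)),
    class = "analysis_matrix")
}

invert_scores_quiet <- function(cohort, schema) {
  if (isTRUE(attr(cohort, "scores_inverted"))) cohort
  else invert_scores(cohort, schema)
}

#' @export
print.analysis_matrix <- function(x, ...) {
  cat("Analysis matrix: n =", x$n, "participants,",
      ncol(x$Y), "standardized outcomes,",
      ncol(x$C), "covariate column(s)\n")
  cat("  missing outcome cells:", sum(is.na(x$Y)), "\n")
  invisible(x)
}

#' Export the standardized analysis matrix for audit
#'
#' @param am An `analysis_matrix`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_analysis_matrix <- function(am, path) {
  df <- data.frame(x = am$x, am$Y, check.names = FALSE)
  if (ncol(am$C)) df <- cbind(df, as.data.frame(am$C))
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}
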