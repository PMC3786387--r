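#' Configuration of the synthetic-cohort generator
#'
#' Defaults emulate the reference cohort: n = 219 with exactly 141 women,
#' covariates and the 18 outcomes moment-matched to the published summary
#' table, a weak negative NART-S100B association (-0.004 ng/mL per error),
#' a negligible age-S100B slope (-0.001 ng/mL per year), no sex effect, and
#' a latent cognition factor aligned with standardized S100B whose overall
#' standardized slope is `beta_overall`.
#'
#' @param n Cohort size.
#' @param seed Integer seed; the generated table is a pure function of
#'   `(config, seed)`.
#' @param beta_overall True overall standardized slope of outcomes on
#'   standardized S100B.
#' @param domain_dev_sd,outcome_dev_sd SDs of the true domain-level and
#'   outcome-level slope deviations around `beta_overall`.
#' @param noise_df Degrees of freedom of the Student-t outcome noise
#'   (scaled to unit variance); must exceed 2.
#' @param prop_female Fraction of women; the realised count is exact
#'   (`round(prop_female * n)`), not binomial.
#' @param nart_slope NART effect on S100B, ng/mL per error.
#' @param age_slope Age effect on S100B, ng/mL per year.
#' @param nart_cognition_effect Standardized direct effect of NART errors on
#'   every outcome (0 by default; set negative to emulate premorbid-ability
#'   confounding for sensitivity analyses).
#' @param domain_factor_sd SD of optional domain-shared latent factors
#'   (default 0 = single biomarker-aligned factor only).
#' @param missing_rate Fraction of outcome cells masked missing at random.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = 219L, seed = 1L, beta_overall = 0.15,
                             domain_dev_sd = 0.05, outcome_dev_sd = 0.05,
                             noise_df = 8, prop_female = 141 / 219,
                             nart_slope = -0.004, age_slope = -0.001,
                             nart_cognition_effect = 0, domain_factor_sd = 0,
                             missing_rate = 0) {
  cfg <- list(n = as.integer(n), seed = as.integer(seed),
              beta_overall = beta_overall, domain_dev_sd = domain_dev_sd,
              outcome_dev_sd = outcome_dev_sd, noise_df = noise_df,
              prop_female = prop_female, nart_slope = nart_slope,
              age_slope = age_slope,
              nart_cognition_effect = nart_cognition_effect,
              domain_factor_sd = domain_factor_sd,
              missing_rate = missing_rate)
  if (cfg$n < 10L) stop("n must be at least 10")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 0.5)
    stop("missing_rate must lie in [0, 0.5)")
  if (cfg$noise_df <= 2) stop("noise_df must exceed 2 (finite variance)")
  if (cfg$domain_dev_sd < 0 || cfg$outcome_dev_sd < 0)
    stop("deviation SDs must be non-negative")
  class(cfg) <- "generator_config"
  cfg
}

# ---------------------------------------------------------------------------
# Moment matching.
#
# Generated variables are affine transforms of a base variate, clipped to the
# published observed range and (for integer scores) rounded.  Clipping and
# rounding shift the moments, so the affine location/scale is solved
# numerically such that the post-clipping moments reproduce the published
# (observed, hence range-limited) mean and SD.  The solve runs on a large
# fixed-seed base sample, making it deterministic and independent of the
# user's RNG stream.
# ---------------------------------------------------------------------------

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# run expr with a fixed RNG seed, then restore the caller's RNG state
with_fixed_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Solve (m, s) so that mean/sd of fn(m, s) match the targets.
solve_moments <- function(fn, target_mean, target_sd,
                          init = c(target_mean, target_sd)) {
  obj <- function(p) {
    y <- fn(p[1], abs(p[2]))
    ((mean(y) - target_mean) / target_sd)^2 + ((stats::sd(y) - target_sd) / target_sd)^2
  }
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  # refine from a second start if the first stalls on a plateau
  if (fit$value > 1e-6) {
    fit2 <- stats::optim(c(target_mean, 1.5 * target_sd), obj,
                         method = "Nelder-Mead",
                         control = list(maxit = 600, reltol = 1e-10))
    if (fit2$value < fit$value) fit <- fit2
  }
  y <- fn(fit$par[1], abs(fit$par[2]))
  list(m = fit$par[1], s = abs(fit$par[2]),
       achieved_mean = mean(y), achieved_sd = stats::sd(y),
       objective = fit$value)
}

cal_transform <- function(z, m, s, lo, hi, integer) {
  y <- clip(m + s * z, lo, hi)
  if (integer) y <- round(y)
  y
}

.calibration_cache <- new.env(parent = emptyenv())

# Deterministic moment-matching calibration for a generator configuration.
# Cached per configuration (n, seed, prop_female, missing_rate do not enter).
generator_calibration <- function(config, m_samples = 60000L) {
  key <- paste(config$beta_overall, config$domain_dev_sd,
               config$outcome_dev_sd, config$noise_df, config$nart_slope,
               config$age_slope, config$nart_cognition_effect,
               config$domain_factor_sd, m_samples, sep = "|")
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) return(hit)

  cal <- with_fixed_rng(20130930L, {
    tab <- table1_calibration()
    schema <- domain_schema()
    M <- m_samples
    solve_var <- function(variable, z, offset = 0) {
      e <- calibration_entry(variable, tab)
      sol <- solve_moments(function(m, s) {
        y <- clip(m + offset + s * z, e$min, e$max)
        if (e$integer) round(y) else y
      }, e$mean, e$sd)
      sol$lo <- e$min; sol$hi <- e$max; sol$integer <- e$integer
      sol
    }

    age_cal  <- solve_var("age", stats::rnorm(M))
    nart_cal <- solve_var("nart_errors", stats::rnorm(M))
    mmse_cal <- solve_var("mmse", stats::rnorm(M))

    age_s  <- cal_transform(stats::rnorm(M), age_cal$m, age_cal$s,
                            age_cal$lo, age_cal$hi, FALSE)
    nart_s <- cal_transform(stats::rnorm(M), nart_cal$m, nart_cal$s,
                            nart_cal$lo, nart_cal$hi, TRUE)
    offset <- config$age_slope * (age_s - 64.9) +
      config$nart_slope * (nart_s - 14.1)
    s100b_cal <- solve_var("s100b", stats::rnorm(M), offset = offset)

    s100b_s <- clip(s100b_cal$m + offset + s100b_cal$s * stats::rnorm(M),
                    s100b_cal$lo, s100b_cal$hi)
    x_s <- as.vector(scale(s100b_s))
    w_s <- as.vector(scale(nart_s))
    rho <- stats::cor(x_s, w_s)

    theta_ref <- sqrt(config$beta_overall^2 + config$domain_dev_sd^2 +
                        config$outcome_dev_sd^2)
    kappa <- config$nart_cognition_effect
    lambda <- config$domain_factor_sd
    t_scale <- sqrt((config$noise_df - 2) / config$noise_df)
    z_raw <- theta_ref * x_s + kappa * w_s +
      lambda * stats::rnorm(M) +
      t_scale * stats::rt(M, df = config$noise_df)
    z_sd <- stats::sd(z_raw)
    z_norm <- (z_raw - mean(z_raw)) / z_sd

    outcomes <- lapply(seq_len(nrow(schema)), function(j) {
      e <- calibration_entry(schema$outcome[j], tab)
      sgn <- if (schema$invert[j]) -1 else 1
      sol <- solve_moments(function(m, s)
        cal_transform(sgn * z_norm, m, s, e$min, e$max, e$integer),
        e$mean, e$sd)
      sol$lo <- e$min; sol$hi <- e$max
      sol$integer <- e$integer; sol$sign <- sgn
      sol
    })
    names(outcomes) <- schema$outcome

    list(age = age_cal, nart = nart_cal, mmse = mmse_cal, s100b = s100b_cal,
         outcomes = outcomes, rho_x_nart = rho, theta_ref = theta_ref,
         var_ref = theta_ref^2 + kappa^2 + 2 * theta_ref * kappa * rho +
           lambda^2 + 1,
         z_sd_ref = z_sd, t_scale = t_scale)
  })
  .calibration_cache[[key]] <- cal
  cal
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a cohort whose observed moments reproduce the published cohort
#' summary table.  Covariates are moment-matched clipped normals (NART and
#' MMSE rounded to integers); S100B depends weakly and negatively on age and
#' NART; each standardized outcome is driven by standardized S100B through
#' the outcome's true slope `theta_j = beta_overall + domain_dev + outcome
#' dev` plus unit-variance Student-t noise, then affinely mapped onto the
#' published mean/SD, orientation-flipped for lower-is-better scores, range
#' clipped, and rounded where the instrument yields integers.
#'
#' @param config A [generator_config()].
#' @return A list with `cohort` (a `cohort_table`) and `truth` (a
#'   `true_parameters` list: `beta_overall`, `domain_devs`, `outcome_devs`,
#'   per-outcome true slopes `theta`, covariate slopes, seed).
#' @examples
#' g <- generate_cohort(generator_config(n = 50, seed = 7))
#' nrow(g$cohort); g$truth$beta_overall
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  schema <- domain_schema()
  dom <- domain_index(schema)
  cal <- generator_calibration(config)

  set.seed(config$seed)
  n <- config$n

  delta <- stats::rnorm(5, 0, config$domain_dev_sd)
  eps <- stats::rnorm(18, 0, config$outcome_dev_sd)
  theta <- config$beta_overall + delta[dom] + eps

  n_f <- round(config$prop_female * n)
  sex <- sample(c(rep("F", n_f), rep("M", n - n_f)))

  age  <- cal_transform(stats::rnorm(n), cal$age$m, cal$age$s,
                        cal$age$lo, cal$age$hi, FALSE)
  nart <- cal_transform(stats::rnorm(n), cal$nart$m, cal$nart$s,
                        cal$nart$lo, cal$nart$hi, TRUE)
  mmse <- cal_transform(stats::rnorm(n), cal$mmse$m, cal$mmse$s,
                        cal$mmse$lo, cal$mmse$hi, TRUE)
  s100b <- clip(cal$s100b$m +
                  config$age_slope * (age - 64.9) +
                  config$nart_slope * (nart - 14.1) +
                  cal$s100b$s * stats::rnorm(n),
                cal$s100b$lo, cal$s100b$hi)

  x <- as.vector(scale(s100b))
  w <- as.vector(scale(nart))
  kappa <- config$nart_cognition_effect
  lambda <- config$domain_factor_sd
  f_dom <- if (lambda > 0) matrix(stats::rnorm(n * 5), n, 5) else NULL

  scores <- matrix(NA_real_, n, 18, dimnames = list(NULL, schema$outcome))
  noise <- matrix(stats::rt(n * 18, df = config$noise_df), n, 18) * cal$t_scale
  for (j in seq_len(18)) {
    var_j <- theta[j]^2 + kappa^2 + 2 * theta[j] * kappa * cal$rho_x_nart +
      lambda^2 + 1
    norm_j <- cal$z_sd_ref * sqrt(var_j / cal$var_ref)
    z <- (theta[j] * x + kappa * w +
            (if (is.null(f_dom)) 0 else lambda * f_dom[, dom[j]]) +
            noise[, j]) / norm_j
    oc <- cal$outcomes[[j]]
    scores[, j] <- cal_transform(oc$sign * z, oc$m, oc$s,
                                 oc$lo, oc$hi, oc$integer)
  }

  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * 18) < config$missing_rate, n, 18)
    scores[mask] <- NA_real_
  }

  cohort <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    s100b = s100b, age = age, sex = sex,
    nart_errors = nart, mmse = mmse,
    stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(scores))
  cohort <- as_cohort_table(cohort)

  truth <- structure(list(
    beta_overall = config$beta_overall,
    domain_devs = delta, outcome_devs = eps,
    theta = stats::setNames(theta, schema$outcome),
    age_slope = config$age_slope, nart_slope = config$nart_slope,
    nart_cognition_effect = kappa,
    noise_df = config$noise_df, seed = config$seed,
    calibration = lapply(cal$outcomes, function(o)
      c(m = o$m, s = o$s, achieved_mean = o$achieved_mean,
        achieved_sd = o$achieved_sd))),
    class = "true_parameters")

  list(cohort = cohort, truth = truth)
}

#' Generate a null cohort (no biomarker-cognition effect)
#'
#' Identical to [generate_cohort()] with `beta_overall`, `domain_dev_sd` and
#' `outcome_dev_sd` all forced to zero: outcomes are pure noise with the
#' published moments, for type-S / type-M error studies.
#'
#' @param config A [generator_config()]; its slope fields are overridden.
#' @return As [generate_cohort()].
#' @export
null_cohort <- function(config = generator_config()) {
  config$beta_overall <- 0
  config$domain_dev_sd <- 0
  config$outcome_dev_sd <- 0
  generate_cohort(config)
}

#' Export generator ground truth as JSON
#'
#' @param truth A `true_parameters` list from [generate_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_true_parameters <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
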