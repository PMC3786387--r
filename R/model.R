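#' Prior hyperparameters of the nested-domain model
#'
#' Weakly-informative priors for standardized data: the overall slope,
#' intercepts and covariate coefficients get normal(0, `overarching_sd`^2)
#' priors; the domain- and outcome-level deviation SDs get half-Cauchy(0,
#' `hyper_cauchy_scale`) priors; each outcome's residual scale gets a
#' uniform(0, `sigma_upper`) prior; and the reciprocal of the t degrees of
#' freedom gets a uniform(`inv_df_lower`, `inv_df_upper`) prior, so nu
#' ranges over (2, 1000).
#'
#' @param overarching_sd SD of the normal prior on location coefficients.
#' @param hyper_cauchy_scale Scale of the half-Cauchy hyperpriors.
#' @param sigma_upper Upper bound of the uniform residual-scale prior.
#' @param inv_df_lower,inv_df_upper Bounds of the uniform prior on 1/nu.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(overarching_sd = 100, hyper_cauchy_scale = 25,
                       sigma_upper = 100, inv_df_lower = 0.001,
                       inv_df_upper = 0.5) {
  stopifnot(overarching_sd > 0, hyper_cauchy_scale > 0, sigma_upper > 0,
            inv_df_lower > 0, inv_df_lower < inv_df_upper)
  structure(list(overarching_sd = overarching_sd,
                 hyper_cauchy_scale = hyper_cauchy_scale,
                 sigma_upper = sigma_upper,
                 inv_df_lower = inv_df_lower,
                 inv_df_upper = inv_df_upper),
            class = "prior_spec")
}

#' Specification of the nested-domain robust regression model
#'
#' The outcome-level standardized slope decomposes additively as
#' `theta_j = beta + delta_d(j) + eps_j` (non-centered parameterization of
#' the nesting `theta_j ~ N(beta_d, sigma_outcome)`,
#' `beta_d ~ N(beta, sigma_domain)`).  Residuals are Student-t with a
#' shared degrees-of-freedom parameter sampled on the reciprocal scale.
#'
#' @param schema A [domain_schema()]; may also be a reduced schema for
#'   single-outcome regressions.
#' @param covariates Character subset of `c("age", "sex", "nart")`; must
#'   match the analysis matrix the model is fitted to.
#' @param priors A [prior_spec()].
#' @param hierarchical If `FALSE`, the domain/outcome deviation layers are
#'   removed (`theta_j = beta`), as used for single-outcome regressions and
#'   conjugate-limit checks.
#' @param intercept Include per-outcome intercepts (default `TRUE`).
#' @param per_outcome_nu Estimate a separate degrees-of-freedom parameter
#'   per outcome instead of one shared nu (default `FALSE`).
#' @param fix_sigma Optional fixed residual scale(s) (scalar or length-J);
#'   removes sigma from the sampled parameters.
#' @param fix_nu Optional fixed degrees of freedom; removes nu from the
#'   sampled parameters (e.g. `fix_nu = 1000` for an effectively normal
#'   likelihood).
#' @return A `model_spec` list.
#' @export
model_spec <- function(schema = domain_schema(),
                       covariates = character(),
                       priors = prior_spec(),
                       hierarchical = TRUE,
                       intercept = TRUE,
                       per_outcome_nu = FALSE,
                       fix_sigma = NULL,
                       fix_nu = NULL) {
  stopifnot(inherits(priors, "prior_spec"),
            all(covariates %in% c("age", "sex", "nart")))
  J <- nrow(schema)
  if (!is.null(fix_sigma)) {
    fix_sigma <- rep_len(fix_sigma, J)
    stopifnot(all(fix_sigma > 0))
  }
  if (!is.null(fix_nu)) stopifnot(fix_nu > 0)
  structure(list(schema = schema, covariates = covariates, priors = priors,
                 hierarchical = hierarchical, intercept = intercept,
                 per_outcome_nu = per_outcome_nu,
                 fix_sigma = fix_sigma, fix_nu = fix_nu),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Nested-domain robust regression model\n")
  cat("  outcomes:", nrow(x$schema),
      if (x$hierarchical) sprintf("in %d domains (hierarchical)",
                                  length(unique(x$schema$domain)))
      else "(non-hierarchical)", "\n")
  cat("  covariates:", if (length(x$covariates))
    paste(x$covariates, collapse = ", ") else "none", "\n")
  cat("  t degrees of freedom:",
      if (!is.null(x$fix_nu)) paste("fixed at", x$fix_nu)
      else if (x$per_outcome_nu) "per outcome" else "shared", "\n")
  invisible(x)
}

#' Construct a parameter state
#'
#' A single point in the model's parameter space.  `u = 1/nu` is the
#' sampled degrees-of-freedom parameter (uniform prior on `u`, so no
#' Jacobian is needed on this scale).
#'
#' @param beta Overall standardized slope.
#' @param delta Domain slope deviations (length = number of domains).
#' @param eps Outcome slope deviations (length J).
#' @param alpha Outcome intercepts (length J).
#' @param gamma J x k matrix of covariate coefficients.
#' @param sigma Residual scales (length J).
#' @param sigma_domain,sigma_outcome Hierarchical deviation SDs.
#' @param u Reciprocal degrees of freedom (scalar, or length J under
#'   per-outcome nu).
#' @return A `parameter_state` list.
#' @export
parameter_state <- function(beta = 0, delta = numeric(5), eps = numeric(18),
                            alpha = numeric(18),
                            gamma = matrix(0, 18, 0),
                            sigma = rep(1, 18),
                            sigma_domain = 1, sigma_outcome = 1, u = 0.1) {
  structure(list(beta = beta, delta = delta, eps = eps, alpha = alpha,
                 gamma = gamma, sigma = sigma, sigma_domain = sigma_domain,
                 sigma_outcome = sigma_outcome, u = u),
            class = "parameter_state")
}

#' Slope implied for one outcome or one domain
#'
#' `outcome_slope` returns `theta_j = beta + delta_d(j) + eps_j`;
#' `domain_slope` returns `beta + delta_d`.
#'
#' @param state A [parameter_state()].
#' @param j Outcome index (1-based, schema order).
#' @param d Domain index (1-based).
#' @param schema The [domain_schema()] defining the outcome-domain map.
#' @return A single slope value.
#' @export
outcome_slope <- function(state, j, schema = domain_schema()) {
  if (j < 1 || j > length(state$eps)) stop("outcome index out of range")
  d <- domain_index(schema)[j]
  state$beta + (if (length(state$delta)) state$delta[d] else 0) + state$eps[j]
}

#' @rdname outcome_slope
#' @export
domain_slope <- function(state, d) {
  if (d < 1 || d > length(state$delta)) stop("domain index out of range")
  state$beta + state$delta[d]
}

# location-scale Student-t log density
dt_ls <- function(x, mu, sigma, nu) {
  stats::dt((x - mu) / sigma, df = nu, log = TRUE) - log(sigma)
}

# half-Cauchy(0, scale) log density
dhalfcauchy_log <- function(x, scale) {
  ifelse(x < 0, -Inf, log(2) - log(pi * scale * (1 + (x / scale)^2)))
}

state_nu <- function(state) 1 / state$u

#' Model log-likelihood
#'
#' Sum over all non-missing outcome cells of the location-scale Student-t
#' log density with location `alpha_j + theta_j * x_i + C_i %*% gamma_j`,
#' scale `sigma_j` and degrees of freedom `1/u`.
#'
#' @param state A [parameter_state()].
#' @param data An `analysis_matrix` from [build_analysis_matrix()].
#' @param model A [model_spec()].
#' @return The log-likelihood (finite for valid states).
#' @export
log_likelihood <- function(state, data, model = model_spec(data$schema)) {
  if (!all(is.finite(data$x)) || !all(is.finite(data$Y) | is.na(data$Y)))
    stop("analysis matrix contains non-finite values")
  J <- ncol(data$Y)
  nu <- if (!is.null(model$fix_nu)) rep_len(model$fix_nu, J)
        else rep_len(1 / state$u, J)
  sigma <- if (!is.null(model$fix_sigma)) model$fix_sigma else state$sigma
  dom <- domain_index(model$schema)
  total <- 0
  for (j in seq_len(J)) {
    obs <- !is.na(data$Y[, j])
    theta_j <- if (model$hierarchical)
      state$beta + state$delta[dom[j]] + state$eps[j] else state$beta
    mu <- theta_j * data$x[obs]
    if (model$intercept) mu <- mu + state$alpha[j]
    if (ncol(data$C) > 0)
      mu <- mu + as.vector(data$C[obs, , drop = FALSE] %*% state$gamma[j, ])
    total <- total + sum(dt_ls(data$Y[obs, j], mu, sigma[j], nu[j]))
  }
  total
}

#' Model log-prior
#'
#' Normal(0, overarching_sd^2) on the overall slope, intercepts and
#' covariate coefficients; normal(0, sigma_domain^2) and normal(0,
#' sigma_outcome^2) on the domain and outcome deviations; half-Cauchy on
#' both deviation SDs; uniform(0, sigma_upper) on residual scales; uniform
#' on `u = 1/nu` (sampled directly on the `u` scale).  Returns `-Inf`
#' outside the support.
#'
#' @inheritParams log_likelihood
#' @return The log prior density.
#' @export
log_prior <- function(state, model = model_spec()) {
  p <- model$priors
  lp <- stats::dnorm(state$beta, 0, p$overarching_sd, log = TRUE)
  if (model$intercept)
    lp <- lp + sum(stats::dnorm(state$alpha, 0, p$overarching_sd, log = TRUE))
  if (length(state$gamma))
    lp <- lp + sum(stats::dnorm(state$gamma, 0, p$overarching_sd, log = TRUE))
  if (model$hierarchical) {
    if (state$sigma_domain <= 0 || state$sigma_outcome <= 0) return(-Inf)
    lp <- lp + dhalfcauchy_log(state$sigma_domain, p$hyper_cauchy_scale) +
      dhalfcauchy_log(state$sigma_outcome, p$hyper_cauchy_scale) +
      sum(stats::dnorm(state$delta, 0, state$sigma_domain, log = TRUE)) +
      sum(stats::dnorm(state$eps, 0, state$sigma_outcome, log = TRUE))
  }
  if (is.null(model$fix_sigma)) {
    if (any(state$sigma <= 0 | state$sigma >= p$sigma_upper)) return(-Inf)
    lp <- lp + length(state$sigma) * stats::dunif(1, 0, p$sigma_upper,
                                                  log = TRUE)
  }
  if (is.null(model$fix_nu)) {
    if (any(state$u < p$inv_df_lower | state$u > p$inv_df_upper)) return(-Inf)
    lp <- lp + length(state$u) *
      stats::dunif(mean(state$u), p$inv_df_lower, p$inv_df_upper, log = TRUE)
  }
  lp
}

#' Model log-posterior (unnormalized)
#'
#' @inheritParams log_likelihood
#' @return `log_likelihood + log_prior`; `-Inf` propagates from the prior.
#' @export
log_posterior <- function(state, data, model = model_spec(data$schema)) {
  lp <- log_prior(state, model)
  if (!is.finite(lp)) return(lp)
  lp + log_likelihood(state, data, model)
}

#' Serialize a model specification to YAML
#'
#' @param model A [model_spec()].
#' @param path Output path; if `NULL`, the YAML string is returned.
#' @return The YAML string (invisibly when written to a file).
#' @export
model_spec_to_yaml <- function(model, path = NULL) {
  obj <- list(covariates = as.list(model$covariates),
              hierarchical = model$hierarchical,
              intercept = model$intercept,
              per_outcome_nu = model$per_outcome_nu,
              fix_sigma = model$fix_sigma, fix_nu = model$fix_nu,
              priors = unclass(model$priors))
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a model specification from YAML
#'
#' @param path YAML file path.
#' @param schema A [domain_schema()].
#' @return A [model_spec()].
#' @export
model_spec_from_yaml <- function(path, schema = domain_schema()) {
  obj <- yaml::read_yaml(path)
  pr <- do.call(prior_spec, obj$priors %||% list())
  model_spec(schema = schema,
             covariates = unlist(obj$covariates) %||% character(),
             priors = pr,
             hierarchical = obj$hierarchical %||% TRUE,
             intercept = obj$intercept %||% TRUE,
             per_outcome_nu = obj$per_outcome_nu %||% FALSE,
             fix_sigma = obj$fix_sigma, fix_nu = obj$fix_nu)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
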