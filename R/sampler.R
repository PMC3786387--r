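#' MCMC schedule configuration
#'
#' The default schedule follows the published analysis: 5000 adaptation
#' steps, 50,000 burn-in steps, and 50,000 saved samples (thinned every
#' tenth step) across three chains.  Because 50,000 is not divisible by 3,
#' each chain saves `round(saved_samples_total / n_chains)` draws (16,667
#' at the defaults).  Two scaled-down presets are provided for testing and
#' quick analyses; effective-sample-size gates should be pro-rated by the
#' saved-draw count when a preset is used.
#'
#' @param n_chains Number of chains.
#' @param adapt_steps Adaptation iterations (proposal scales tune here and
#'   then freeze).
#' @param burnin_steps Discarded post-adaptation iterations.
#' @param saved_samples_total Saved draws summed over chains.
#' @param thin Thinning interval.
#' @param seed Master seed; chain `c` runs on stream
#'   `(seed * 1009 + c) mod (2^31 - 1)`.
#' @param preset One of `"paper"` (the default schedule above), `"reduced"`
#'   (3 chains, 2000/8000, 15,000 saved, thin 5) or `"test"` (3 chains,
#'   500/2000, 1500 saved, thin 2); explicit arguments override the preset.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = NULL, adapt_steps = NULL,
                        burnin_steps = NULL, saved_samples_total = NULL,
                        thin = NULL, seed = 1L,
                        preset = c("paper", "reduced", "test")) {
  preset <- match.arg(preset)
  base <- switch(preset,
    paper   = list(n_chains = 3L, adapt_steps = 5000L, burnin_steps = 50000L,
                   saved_samples_total = 50000L, thin = 10L),
    reduced = list(n_chains = 3L, adapt_steps = 2000L, burnin_steps = 8000L,
                   saved_samples_total = 15000L, thin = 5L),
    test    = list(n_chains = 3L, adapt_steps = 500L, burnin_steps = 2000L,
                   saved_samples_total = 1500L, thin = 2L))
  cfg <- list(
    n_chains = as.integer(n_chains %||% base$n_chains),
    adapt_steps = as.integer(adapt_steps %||% base$adapt_steps),
    burnin_steps = as.integer(burnin_steps %||% base$burnin_steps),
    saved_samples_total = as.integer(saved_samples_total %||%
                                       base$saved_samples_total),
    thin = as.integer(thin %||% base$thin),
    seed = as.integer(seed), preset = preset)
  stopifnot(cfg$n_chains >= 1L, cfg$adapt_steps >= 1L, cfg$burnin_steps >= 1L,
            cfg$saved_samples_total >= cfg$n_chains, cfg$thin >= 1L)
  cfg$saved_per_chain <- as.integer(round(cfg$saved_samples_total /
                                            cfg$n_chains))
  class(cfg) <- "mcmc_config"
  cfg
}

chain_seed <- function(master, chain) {
  as.integer((as.numeric(master) * 1009 + chain) %% 2147483647)
}

# parameter names in packed-vector order (must mirror src/sampler.cpp)
parameter_names <- function(model) {
  J <- nrow(model$schema)
  D <- length(unique(model$schema$domain))
  k <- length(model$covariates)
  nm <- c("beta",
          paste0("delta[", seq_len(D), "]"),
          paste0("eps[", seq_len(J), "]"),
          paste0("alpha[", seq_len(J), "]"))
  if (k > 0)
    nm <- c(nm, as.vector(vapply(model$covariates, function(cv)
      paste0("gamma[", seq_len(J), ",", cv, "]"), character(J))))
  nm <- c(nm, paste0("sigma[", seq_len(J), "]"),
          "sigma_domain", "sigma_outcome")
  if (model$per_outcome_nu) c(nm, paste0("u[", seq_len(J), "]"))
  else c(nm, "u")
}

pack_state <- function(state, model) {
  v <- c(state$beta, state$delta, state$eps, state$alpha,
         as.vector(state$gamma), state$sigma,
         state$sigma_domain, state$sigma_outcome, state$u)
  stats::setNames(v, parameter_names(model))
}

unpack_state <- function(v, model) {
  J <- nrow(model$schema)
  D <- length(unique(model$schema$domain))
  k <- length(model$covariates)
  p <- 1L
  take <- function(len) {
    out <- v[p:(p + len - 1L)]; p <<- p + len; out
  }
  parameter_state(
    beta = take(1L), delta = take(D), eps = take(J), alpha = take(J),
    gamma = matrix(if (k > 0) take(J * k) else numeric(0), J, k,
                   dimnames = list(NULL, model$covariates)),
    sigma = take(J), sigma_domain = take(1L), sigma_outcome = take(1L),
    u = take(if (model$per_outcome_nu) J else 1L))
}

#' Initialize a parameter state from least squares
#'
#' Per-outcome ordinary least-squares fits (on the standardized data) seed
#' the intercepts, covariate coefficients and slope decomposition; residual
#' SDs seed the scales.  A seed-controlled jitter overdisperses chain
#' starting points so the Gelman-Rubin diagnostic is meaningful.
#'
#' @param model A [model_spec()].
#' @param data An `analysis_matrix`.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @param jitter_sd SD of the additive jitter on location parameters.
#' @return A [parameter_state()].
#' @export
initialize_state <- function(model, data, seed = NULL, jitter_sd = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  J <- ncol(data$Y)
  D <- length(unique(model$schema$domain))
  k <- ncol(data$C)
  dom <- domain_index(model$schema)
  slopes <- numeric(J); alpha <- numeric(J)
  gamma <- matrix(0, J, k, dimnames = list(NULL, model$covariates))
  sigma <- numeric(J)
  for (j in seq_len(J)) {
    obs <- !is.na(data$Y[, j])
    if (sum(obs) < k + 3L) stop("too few observed cells in outcome ", j)
    X <- cbind(1, data$x[obs],
               if (k > 0) data$C[obs, , drop = FALSE])
    fit <- stats::lm.fit(X, data$Y[obs, j])
    if (any(is.na(fit$coefficients)))
      stop("degenerate design (zero-variance column) in outcome ", j)
    alpha[j] <- fit$coefficients[1]
    slopes[j] <- fit$coefficients[2]
    if (k > 0) gamma[j, ] <- fit$coefficients[-(1:2)]
    sigma[j] <- stats::sd(fit$residuals)
    if (!is.finite(sigma[j]) || sigma[j] <= 0) sigma[j] <- 1
  }
  beta <- mean(slopes)
  if (model$hierarchical) {
    dmean <- tapply(slopes, dom, mean)[as.character(seq_len(D))]
    dmean[is.na(dmean)] <- beta
    delta <- as.numeric(dmean) - beta
    eps <- slopes - beta - delta[dom]
  } else {
    delta <- numeric(D); eps <- numeric(J)
  }
  jit <- function(v) v + stats::rnorm(length(v), 0, jitter_sd)
  st <- parameter_state(
    beta = jit(beta),
    delta = if (model$hierarchical) jit(delta) else delta,
    eps = if (model$hierarchical) jit(eps) else eps,
    alpha = if (model$intercept) jit(alpha) else numeric(J),
    gamma = if (k > 0) gamma + stats::rnorm(length(gamma), 0, jitter_sd)
            else gamma,
    sigma = if (is.null(model$fix_sigma))
      pmin(pmax(sigma * exp(stats::rnorm(J, 0, 0.1)), 0.01),
           model$priors$sigma_upper * 0.99) else model$fix_sigma,
    sigma_domain = 1, sigma_outcome = 1,
    u = rep(stats::runif(if (model$per_outcome_nu) J else 1, 0.05, 0.3), 1))
  st
}

#' Export a parameter state as flat named-parameter JSON
#'
#' @param state A [parameter_state()].
#' @param model The [model_spec()] defining the parameter layout.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_parameter_state <- function(state, model, path) {
  v <- pack_state(state, model)
  jsonlite::write_json(as.list(v), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# compiled-density entry point (used by consistency tests)
run_cpp_log_posterior <- function(state, data, model) {
  cpp_log_posterior(pack_state(state, model), data$x, data$Y, data$C,
                    domain_index(model$schema),
                    length(unique(model$schema$domain)), cpp_opts(model))
}

cpp_opts <- function(model) {
  p <- model$priors
  list(hierarchical = model$hierarchical, intercept = model$intercept,
       per_outcome_nu = model$per_outcome_nu,
       fix_sigma = model$fix_sigma, fix_nu = model$fix_nu,
       priors = c(p$overarching_sd, p$hyper_cauchy_scale, p$sigma_upper,
                  p$inv_df_lower, p$inv_df_upper))
}

#' Run the adaptive Metropolis-within-Gibbs sampler
#'
#' Draws posterior samples from the nested-domain robust regression model.
#' Updates are blocked as: per-outcome (intercept + covariate coefficients),
#' per-outcome slope deviation, per-outcome residual scale, overall slope,
#' per-domain deviation, the two hierarchical deviation SDs, and the
#' reciprocal degrees of freedom.  Proposal scales adapt toward 40%
#' acceptance during `adapt_steps` iterations, then freeze.  Runs are fully
#' reproducible from `config$seed`.
#'
#' @param model A [model_spec()].
#' @param data An `analysis_matrix` consistent with the model.
#' @param config An [mcmc_config()].
#' @return A `posterior_samples` object: `draws` is a `chains x iterations
#'   x parameters` array; `acceptance` holds post-adaptation acceptance
#'   rates per block and chain; `config`, `model` and `seeds` record
#'   provenance.
#' @export
run_mcmc <- function(model, data, config = mcmc_config()) {
  stopifnot(inherits(model, "model_spec"), inherits(data, "analysis_matrix"),
            inherits(config, "mcmc_config"))
  if (length(model$covariates) != ncol(data$C))
    stop("model covariate set does not match the analysis matrix")
  pn <- parameter_names(model)
  dom <- domain_index(model$schema)
  D <- length(unique(model$schema$domain))
  opts <- cpp_opts(model)
  draws <- array(NA_real_,
                 dim = c(config$n_chains, config$saved_per_chain, length(pn)),
                 dimnames = list(NULL, NULL, pn))
  acceptance <- vector("list", config$n_chains)
  seeds <- integer(config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    seeds[ch] <- chain_seed(config$seed, ch)
    set.seed(seeds[ch])
    init <- NULL
    for (attempt in seq_len(10L)) {
      cand <- initialize_state(model, data)
      if (is.finite(log_posterior(cand, data, model))) { init <- cand; break }
    }
    if (is.null(init))
      stop("could not find a finite-posterior initial state in 10 attempts")
    res <- run_chain_cpp(data$x, data$Y, data$C, dom, D, opts,
                         pack_state(init, model),
                         config$adapt_steps, config$burnin_steps,
                         config$saved_per_chain, config$thin)
    draws[ch, , ] <- res$draws
    acceptance[[ch]] <- res$acceptance
  }

  structure(list(draws = draws, parameters = pn, model = model,
                 config = config, seeds = seeds, acceptance = acceptance,
                 scaling_record = data$scaling_record),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  d <- dim(x$draws)
  cat("Posterior samples:", d[1], "chains x", d[2], "iterations x",
      d[3], "parameters\n")
  cat("  schedule:", x$config$adapt_steps, "adapt /", x$config$burnin_steps,
      "burn-in / thin", x$config$thin, " (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Pool posterior draws into a matrix
#'
#' @param x A `posterior_samples` object.
#' @param ... Unused.
#' @return An `(iterations * chains) x parameters` matrix.
#' @export
as.matrix.posterior_samples <- function(x, ...) {
  d <- dim(x$draws)
  out <- do.call(rbind, lapply(seq_len(d[1]), function(ch) x$draws[ch, , ]))
  colnames(out) <- x$parameters
  out
}

# chains x iterations matrix for a single (possibly derived) parameter
chain_matrix <- function(post, parameter) {
  dm <- derived_draws(post, parameter)
  dm
}

# returns chains x iterations matrix for raw or derived parameter names:
# theta[j] = beta + delta[dom(j)] + eps[j]; domain[d] = beta + delta[d]; nu.
derived_draws <- function(post, parameter) {
  pn <- post$parameters
  draws <- post$draws
  get <- function(name) {
    i <- match(name, pn)
    if (is.na(i)) stop("unknown parameter '", name, "'")
    draws[, , i, drop = TRUE]
  }
  as_mat <- function(v) {
    if (is.null(dim(v))) matrix(v, nrow = dim(draws)[1]) else v
  }
  if (parameter %in% pn) return(as_mat(get(parameter)))
  m <- regmatches(parameter, regexec("^theta\\[(\\d+)\\]$", parameter))[[1]]
  if (length(m)) {
    j <- as.integer(m[2])
    dom <- domain_index(post$model$schema)
    if (j < 1 || j > length(dom)) stop("outcome index out of range")
    return(as_mat(get("beta") +
                    (if (post$model$hierarchical)
                      get(paste0("delta[", dom[j], "]")) +
                        get(paste0("eps[", j, "]")) else 0)))
  }
  m <- regmatches(parameter, regexec("^domain\\[(\\d+)\\]$", parameter))[[1]]
  if (length(m)) {
    d <- as.integer(m[2])
    return(as_mat(get("beta") +
                    (if (post$model$hierarchical)
                      get(paste0("delta[", d, "]")) else 0)))
  }
  if (parameter == "nu") return(as_mat(1 / get("u")))
  stop("unknown parameter '", parameter, "'")
}

#' Persist posterior samples to disk
#'
#' Writes one CSV per chain (iteration x parameter) plus a JSON manifest
#' with the schedule, seeds and acceptance rates.
#'
#' @param post A `posterior_samples` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_posterior <- function(post, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(post$draws)
  for (ch in seq_len(d[1])) {
    m <- post$draws[ch, , , drop = TRUE]
    colnames(m) <- post$parameters
    utils::write.csv(m, file.path(dir, sprintf("chain%02d.csv", ch)),
                     row.names = FALSE)
  }
  manifest <- list(n_chains = d[1], iterations = d[2],
                   parameters = post$parameters,
                   config = unclass(post$config), seeds = post$seeds,
                   acceptance = post$acceptance)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Reload persisted posterior samples
#'
#' @param dir Directory written by [write_posterior()].
#' @param model The [model_spec()] the samples came from.
#' @return A `posterior_samples` object.
#' @export
read_posterior <- function(dir, model) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^chain\\d+\\.csv$",
                           full.names = TRUE))
  mats <- lapply(files, function(f)
    as.matrix(utils::read.csv(f, check.names = FALSE)))
  draws <- array(NA_real_, c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])),
                 dimnames = list(NULL, NULL, manifest$parameters))
  for (ch in seq_along(mats)) draws[ch, , ] <- mats[[ch]]
  cfg <- manifest$config
  config <- mcmc_config(n_chains = cfg$n_chains, adapt_steps = cfg$adapt_steps,
                        burnin_steps = cfg$burnin_steps,
                        saved_samples_total = cfg$saved_samples_total,
                        thin = cfg$thin, seed = cfg$seed,
                        preset = cfg$preset %||% "paper")
  structure(list(draws = draws, parameters = manifest$parameters,
                 model = model, config = config, seeds = manifest$seeds,
                 acceptance = manifest$acceptance, scaling_record = NULL),
            class = "posterior_samples")
}
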