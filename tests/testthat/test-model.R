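# one-cell analysis matrix (y, x given) for density oracles
one_cell_matrix <- function(y = 0, x = 0.7) {
  schema <- cognest:::single_outcome_schema("y")
  structure(list(
    x = c(x, 0), Y = matrix(c(y, NA), ncol = 1, dimnames = list(NULL, "y")),
    C = matrix(numeric(0), 2, 0), schema = schema, covariates = character(),
    scaling_record = data.frame(column = "y", center = 0, scale = 1,
                                inverted = FALSE),
    n = 2), class = "analysis_matrix")
}

zero_state <- function(J = 1, D = 1, sigma = 1, u = 0.1) {
  parameter_state(beta = 0, delta = numeric(D), eps = numeric(J),
                  alpha = numeric(J), gamma = matrix(0, J, 0),
                  sigma = rep(sigma, J), sigma_domain = 1, sigma_outcome = 1,
                  u = u)
}

test_that("t likelihood matches closed forms in the normal limit and at nu=3", {
  dat <- one_cell_matrix(y = 0)
  ms <- model_spec(schema = dat$schema, hierarchical = FALSE)
  # nu -> 1000: approaches the standard normal log density at 0
  st <- zero_state(u = 1 / 1000)
  expect_equal(log_likelihood(st, dat, ms), log(1 / sqrt(2 * pi)),
               tolerance = 1e-3)
  # nu = 3 closed form: log[Gamma(2) / (Gamma(1.5) sqrt(3 pi))]
  st3 <- zero_state(u = 1 / 3)
  oracle <- lgamma(2) - lgamma(1.5) - 0.5 * log(3 * pi)
  expect_equal(log_likelihood(st3, dat, ms), oracle, tolerance = 1e-12)
})

test_that("masking a cell removes exactly that cell's likelihood term", {
  set.seed(21)
  g <- generate_cohort(generator_config(n = 30, seed = 21))
  am <- build_analysis_matrix(g$cohort)
  ms <- model_spec()
  st <- initialize_state(ms, am, seed = 1)
  full <- log_likelihood(st, am, ms)
  am2 <- am
  am2$Y[5, 3] <- NA
  # the removed term, recomputed independently
  theta3 <- outcome_slope(st, 3)
  mu <- st$alpha[3] + theta3 * am$x[5]
  term <- unname(dt(
    (am$Y[5, 3] - mu) / st$sigma[3], df = 1 / st$u, log = TRUE) -
    log(st$sigma[3]))
  expect_equal(log_likelihood(st, am2, ms), full - term, tolerance = 1e-10)
})

test_that("prior density matches hand-built closed forms and support rules", {
  ms <- model_spec()
  st <- zero_state(J = 18, D = 5)
  # compare against an independently assembled sum
  p <- ms$priors
  expected <- dnorm(0, 0, 100, log = TRUE) * (1 + 18) +     # beta + alphas
    2 * log(2 / (pi * 25 * (1 + (1 / 25)^2))) +             # two half-Cauchys
    sum(dnorm(numeric(5), 0, 1, log = TRUE)) +
    sum(dnorm(numeric(18), 0, 1, log = TRUE)) +
    18 * log(1 / 100) +                                     # sigma ~ U(0,100)
    log(1 / (0.5 - 0.001))                                  # u ~ U(.001,.5)
  expect_equal(log_prior(st, ms), expected, tolerance = 1e-10)

  bad <- st; bad$sigma_domain <- -1
  expect_equal(log_prior(bad, ms), -Inf)
  bad2 <- st; bad2$u <- 0.6                    # 1/nu outside (0.001, 0.5)
  expect_equal(log_prior(bad2, ms), -Inf)
  bad3 <- st; bad3$sigma[4] <- 101
  expect_equal(log_prior(bad3, ms), -Inf)
})

test_that("log posterior is the component sum and rewards better fit", {
  g <- generate_cohort(generator_config(n = 25, seed = 33))
  am <- build_analysis_matrix(g$cohort)
  ms <- model_spec()
  st <- initialize_state(ms, am, seed = 2)
  expect_equal(log_posterior(st, am, ms),
               log_likelihood(st, am, ms) + log_prior(st, ms),
               tolerance = 1e-12)
  expect_true(is.finite(log_posterior(st, am, ms)))

  # halving every residual (at fixed scales) increases the likelihood
  am_half <- am
  for (j in 1:18) {
    theta_j <- outcome_slope(st, j)
    mu <- st$alpha[j] + theta_j * am$x
    am_half$Y[, j] <- mu + (am$Y[, j] - mu) / 2
  }
  expect_gt(log_likelihood(st, am_half, ms), log_likelihood(st, am, ms))
})

test_that("slope decomposition is additive with correct pooling limits", {
  st <- zero_state(J = 18, D = 5)
  st$beta <- 0.2
  st$delta <- c(0.05, 0, 0, 0, 0)
  st$eps[1] <- -0.02
  expect_equal(outcome_slope(st, 1), 0.23)      # outcome 1 is in domain 1
  expect_equal(domain_slope(st, 1), 0.25)
  st$delta[] <- 0; st$eps[] <- 0
  for (j in c(1, 9, 18)) expect_equal(outcome_slope(st, j), st$beta)
  expect_error(outcome_slope(st, 19), "out of range")
  expect_error(domain_slope(st, 0), "out of range")

  # with symmetric deviations the mean outcome slope stays near beta
  set.seed(5)
  ths <- replicate(400, {
    s <- st
    s$delta <- rnorm(5, 0, 0.05); s$eps <- rnorm(18, 0, 0.05)
    mean(sapply(1:18, function(j) outcome_slope(s, j)))
  })
  expect_equal(mean(ths), st$beta, tolerance = 0.005)
})

test_that("log posterior is invariant to relabeling outcomes within a domain", {
  g <- generate_cohort(generator_config(n = 30, seed = 7))
  am <- build_analysis_matrix(g$cohort)
  ms <- model_spec()
  st <- initialize_state(ms, am, seed = 3)
  base <- log_posterior(st, am, ms)
  # swap two secondary-memory outcomes (columns 9 and 10 share domain D3)
  am2 <- am; am2$Y[, c(9, 10)] <- am$Y[, c(10, 9)]
  st2 <- st
  st2$eps[c(9, 10)] <- st$eps[c(10, 9)]
  st2$alpha[c(9, 10)] <- st$alpha[c(10, 9)]
  st2$sigma[c(9, 10)] <- st$sigma[c(10, 9)]
  expect_equal(log_posterior(st2, am2, ms), base, tolerance = 1e-10)
})

test_that("compiled and reference densities agree on random states", {
  g <- generate_cohort(generator_config(n = 40, seed = 13))
  for (cvs in list(character(), c("age", "sex", "nart"))) {
    am <- build_analysis_matrix(g$cohort, covariates = cvs)
    ms <- model_spec(covariates = cvs)
    for (i in 1:4) {
      st <- initialize_state(ms, am, seed = i)
      rlp <- log_posterior(st, am, ms)
      clp <- cognest:::run_cpp_log_posterior(st, am, ms)
      expect_equal(clp, rlp, tolerance = 1e-10)
    }
  }
})

test_that("model specifications serialize to YAML and back", {
  ms <- model_spec(covariates = c("age", "sex"), per_outcome_nu = TRUE,
                   priors = prior_spec(hyper_cauchy_scale = 10))
  p <- tempfile(fileext = ".yaml")
  model_spec_to_yaml(ms, p)
  back <- model_spec_from_yaml(p)
  expect_equal(back$covariates, c("age", "sex"))
  expect_true(back$per_outcome_nu)
  expect_equal(back$priors$hyper_cauchy_scale, 10)
})

test_that("parameter states export to flat named JSON", {
  ms <- model_spec()
  st <- zero_state(J = 18, D = 5)
  st$beta <- 0.2
  p <- tempfile(fileext = ".json")
  write_parameter_state(st, ms, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$beta, 0.2)
  expect_equal(back$`sigma[18]`, 1)
  expect_length(back, length(cognest:::parameter_names(ms)))
})
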