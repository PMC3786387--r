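test_that("runs are bit-identical under the same seed and differ across seeds", {
  dat <- conjugate_fixture(n = 40)
  ms <- model_spec(schema = dat$schema, hierarchical = FALSE)
  cfg <- mcmc_config(n_chains = 2L, adapt_steps = 150L, burnin_steps = 150L,
                     saved_samples_total = 300L, thin = 1L, seed = 7)
  p1 <- run_mcmc(ms, dat, cfg)
  p2 <- run_mcmc(ms, dat, cfg)
  expect_identical(p1$draws, p2$draws)
  cfg2 <- cfg; cfg2$seed <- 8L
  p3 <- run_mcmc(ms, dat, cfg2)
  expect_false(identical(p1$draws, p3$draws))
})

test_that("collapsed model reproduces the conjugate normal posterior", {
  dat <- conjugate_fixture(n = 80, slope = 0.3)
  ms <- model_spec(schema = dat$schema, hierarchical = FALSE,
                   intercept = FALSE, fix_sigma = 1, fix_nu = 1000)
  cfg <- mcmc_config(n_chains = 3L, adapt_steps = 500L, burnin_steps = 1000L,
                     saved_samples_total = 6000L, thin = 2L, seed = 3)
  post <- run_mcmc(ms, dat, cfg)
  bd <- as.vector(cognest:::derived_draws(post, "beta"))
  prec <- sum(dat$x^2) + 1 / 100^2
  closed_mean <- sum(dat$x * dat$Y[, 1]) / prec
  closed_sd <- sqrt(1 / prec)
  ess <- effective_sample_size(t(cognest:::derived_draws(post, "beta")))
  mcse <- closed_sd / sqrt(ess)
  expect_lt(abs(mean(bd) - closed_mean), 3 * mcse)
  expect_lt(abs(sd(bd) - closed_sd), 3 * closed_sd / sqrt(2 * ess))
})

test_that("two-parameter reduced model matches its analytic posterior", {
  # intercept + slope, fixed unit scale, near-normal likelihood: the joint
  # posterior is bivariate normal with precision X'X + I/100^2
  set.seed(14)
  n <- 60
  x <- as.vector(scale(rnorm(n)))
  y <- as.vector(scale(0.4 * x + rnorm(n)))
  dat <- conjugate_fixture(n = n)
  dat$x <- x; dat$Y[, 1] <- y
  ms <- model_spec(schema = dat$schema, hierarchical = FALSE,
                   intercept = TRUE, fix_sigma = 1, fix_nu = 1000)
  cfg <- mcmc_config(n_chains = 3L, adapt_steps = 500L, burnin_steps = 1000L,
                     saved_samples_total = 6000L, thin = 2L, seed = 9)
  post <- run_mcmc(ms, dat, cfg)
  X <- cbind(1, x)
  prec <- crossprod(X) + diag(2) / 100^2
  mu <- solve(prec, crossprod(X, y))
  Sigma <- solve(prec)
  for (i in 1:2) {
    p <- c("alpha[1]", "beta")[i]
    draws <- as.vector(cognest:::derived_draws(post, p))
    ess <- effective_sample_size(t(cognest:::derived_draws(post, p)))
    expect_lt(abs(mean(draws) - mu[i]), 3 * sqrt(Sigma[i, i] / ess))
    expect_lt(abs(sd(draws) - sqrt(Sigma[i, i])),
              3 * sqrt(Sigma[i, i]) / sqrt(2 * ess))
  }
})

test_that("saved draws never leave the prior support", {
  fit <- default_fit()
  m <- as.matrix(fit$post)
  sig <- m[, grep("^sigma\\[", colnames(m))]
  expect_true(all(sig > 0 & sig < 100))
  expect_true(all(m[, "u"] >= 0.001 & m[, "u"] <= 0.5))
  expect_true(all(m[, "sigma_domain"] > 0))
  expect_true(all(m[, "sigma_outcome"] > 0))
  expect_true(all(is.finite(m)))
})

test_that("initialization is finite, overdispersed, and near truth on nulls", {
  g <- default_fit()$gen
  am <- default_fit()$am
  ms <- model_spec()
  s1 <- initialize_state(ms, am, seed = 1)
  s2 <- initialize_state(ms, am, seed = 2)
  expect_true(is.finite(log_posterior(s1, am, ms)))
  expect_false(identical(s1$beta, s2$beta))

  co0 <- null_cohort(generator_config(seed = 77))$cohort
  am0 <- build_analysis_matrix(co0)
  s0 <- initialize_state(ms, am0, seed = 4)
  expect_lt(abs(s0$beta), 0.3)
})

test_that("three short chains agree with one long chain of equal length", {
  dat <- conjugate_fixture(n = 50, slope = 0.2, seed = 6)
  ms <- model_spec(schema = dat$schema, hierarchical = FALSE)
  base <- list(adapt_steps = 400L, burnin_steps = 600L, thin = 2L)
  p3 <- run_mcmc(ms, dat, mcmc_config(n_chains = 3L, adapt_steps = 400L,
                                      burnin_steps = 600L,
                                      saved_samples_total = 4500L, thin = 2L,
                                      seed = 11))
  p1 <- run_mcmc(ms, dat, mcmc_config(n_chains = 1L, adapt_steps = 400L,
                                      burnin_steps = 600L,
                                      saved_samples_total = 4500L, thin = 2L,
                                      seed = 12))
  b3 <- as.vector(cognest:::derived_draws(p3, "beta"))
  b1 <- as.vector(cognest:::derived_draws(p1, "beta"))
  se <- sd(b1) / sqrt(min(effective_sample_size(matrix(b1)),
                          effective_sample_size(t(cognest:::derived_draws(p3, "beta")))))
  expect_lt(abs(mean(b3) - mean(b1)), 4 * se)
})

test_that("posterior samples persist to per-chain CSV plus manifest", {
  fit <- default_fit()
  dir <- file.path(tempdir(), "postdump")
  write_posterior(fit$post, dir)
  expect_setequal(list.files(dir),
                  c("chain01.csv", "chain02.csv", "chain03.csv",
                    "manifest.json"))
  back <- read_posterior(dir, fit$post$model)
  expect_equal(back$draws, fit$post$draws, tolerance = 1e-12)
  expect_equal(back$seeds, fit$post$seeds)
})

test_that("per-outcome degrees of freedom can be switched on", {
  g <- generate_cohort(generator_config(n = 60, seed = 19))
  am <- build_analysis_matrix(g$cohort)
  ms <- model_spec(per_outcome_nu = TRUE)
  cfg <- mcmc_config(n_chains = 2L, adapt_steps = 150L, burnin_steps = 200L,
                     saved_samples_total = 200L, thin = 1L, seed = 5)
  post <- run_mcmc(ms, am, cfg)
  expect_equal(sum(grepl("^u\\[", post$parameters)), 18L)
  m <- as.matrix(post)
  expect_true(all(m[, grep("^u\\[", colnames(m))] >= 0.001))
})
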