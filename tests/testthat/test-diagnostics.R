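test_that("hdi matches brute-force enumeration on vectors up to length 200", {
  expect_equal(unname(hdi(rep(3.2, 25), 0.9)), c(3.2, 3.2))
  expect_equal(unname(hdi(1:100, 0.95)), c(1, 95))
  set.seed(1)
  for (rep in 1:40) {
    n <- sample(20:200, 1)
    samples <- switch(1 + rep %% 3,
                      rnorm(n),
                      rexp(n),
                      sample(0:12, n, replace = TRUE))   # heavy ties
    mass <- runif(1, 0.5, 0.99)
    expect_equal(unname(hdi(samples, mass)), brute_hdi(samples, mass),
                 label = paste("case", rep))
  }
})

test_that("hdi intervals nest as mass grows and match the uniform width", {
  set.seed(2)
  s <- rnorm(5000)
  h50 <- hdi(s, 0.5); h80 <- hdi(s, 0.8); h95 <- hdi(s, 0.95)
  expect_gte(h80[["lower"]], h95[["lower"]]); expect_lte(h80[["upper"]], h95[["upper"]])
  expect_gte(h50[["lower"]], h80[["lower"]]); expect_lte(h50[["upper"]], h80[["upper"]])
  u <- runif(100000)
  h <- hdi(u, 0.95)
  expect_equal(h[["upper"]] - h[["lower"]], 0.95, tolerance = 0.01)
  expect_error(hdi(rnorm(10), 0.9), "at least 20")
  expect_error(hdi(rnorm(50), 1.2), "mass")
})

test_that("identical chains hit the PSRF lower bound exactly", {
  set.seed(3)
  v <- rnorm(500)
  for (m in c(2, 4)) {
    chains <- matrix(rep(v, m), ncol = m)
    expect_equal(gelman_rubin(chains), sqrt(499 / 500), tolerance = 1e-12)
  }
})

test_that("PSRF is near 1 for iid chains and large for separated chains", {
  set.seed(4)
  iid <- matrix(rnorm(40000), ncol = 4)
  expect_equal(gelman_rubin(iid), 1, tolerance = 0.01)
  apart <- cbind(rnorm(500), rnorm(500, 10))
  expect_gt(gelman_rubin(apart), 1.2)
  expect_error(gelman_rubin(matrix(1, 100, 3)), "degenerate")
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "2 chains")
  # split variant flags a trending chain that the plain variant can miss
  trend <- cbind(seq(0, 1, length.out = 400) + rnorm(400, 0, 0.05),
                 seq(0, 1, length.out = 400) + rnorm(400, 0, 0.05))
  expect_gt(gelman_rubin(trend, split = TRUE), gelman_rubin(trend))
})

test_that("effective sample size recovers iid and AR(1) oracles", {
  set.seed(5)
  N <- 20000
  expect_equal(effective_sample_size(matrix(rnorm(N))), N,
               tolerance = 0.1)
  # AR(1), phi = 0.9: integrated autocorrelation time (1+phi)/(1-phi) = 19
  phi <- 0.9
  z <- as.vector(stats::arima.sim(list(ar = phi), n = 100000))
  ess <- effective_sample_size(matrix(z))
  expect_equal(ess, 100000 * (1 - phi) / (1 + phi), tolerance = 0.15)
  expect_error(effective_sample_size(matrix(rep(2, 100))), "degenerate")
  # never exceeds the draw count
  expect_lte(effective_sample_size(matrix(rnorm(3000), ncol = 3)), 3000)
})

test_that("diagnostics broadly agree with the coda implementations", {
  skip_if_not_installed("coda")
  set.seed(6)
  chains <- matrix(as.vector(replicate(3, arima.sim(list(ar = 0.5), 4000))),
                  ncol = 3)
  ours <- gelman_rubin(chains)
  theirs <- coda::gelman.diag(coda::mcmc.list(
    lapply(1:3, function(i) coda::mcmc(chains[, i]))))$psrf[1]
  expect_equal(ours, theirs, tolerance = 0.05)
  ess_ratio <- effective_sample_size(chains) /
    sum(coda::effectiveSize(coda::mcmc.list(
      lapply(1:3, function(i) coda::mcmc(chains[, i])))))
  expect_gt(ess_ratio, 0.5); expect_lt(ess_ratio, 2)
})

test_that("summaries have nested HDIs and are chain-relabeling invariant", {
  fit <- default_fit()
  sm <- summarize_posterior(fit$post, c("beta", "domain[2]", "theta[18]", "nu"))
  expect_equal(nrow(sm), 4L)
  expect_true(all(sm$hdi80_lower >= sm$hdi95_lower))
  expect_true(all(sm$hdi80_upper <= sm$hdi95_upper))
  expect_true(all(sm$ess <= prod(dim(fit$post$draws)[1:2])))
  expect_true(all(sm$psrf >= sqrt((dim(fit$post$draws)[2] - 1) /
                                    dim(fit$post$draws)[2])))
  relabeled <- fit$post
  relabeled$draws <- fit$post$draws[c(3, 1, 2), , ]
  sm2 <- summarize_posterior(relabeled, c("beta", "domain[2]", "theta[18]", "nu"))
  expect_equal(sm2, sm, tolerance = 1e-12)
  expect_error(summarize_posterior(fit$post, "not_a_param"), "unknown")

  p <- tempfile(fileext = ".tsv")
  write_summary(sm, p)
  back <- utils::read.delim(p)
  expect_equal(back$mean, sm$mean, tolerance = 1e-6)
})

test_that("PSRF approaches 1 and ESS approaches N as iid chains grow", {
  set.seed(7)
  gaps <- sapply(c(200, 2000, 20000), function(N) {
    ch <- matrix(rnorm(2 * N), ncol = 2)
    c(abs(gelman_rubin(ch) - 1), abs(effective_sample_size(ch) / (2 * N) - 1))
  })
  expect_lt(gaps[1, 3], gaps[1, 1] + 0.01)
  expect_lt(gaps[2, 3], 0.1)
})
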