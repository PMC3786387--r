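# Shared fixtures, built in code.

# tiny hand-written cohort with all columns (3 participants)
tiny_cohort_df <- function() {
  sc <- outcome_names()
  df <- data.frame(
    participant_id = c("A1", "A2", "A3"),
    s100b = c(0.20, 0.31, 0.15),
    age = c(62.1, 70.5, 55.0),
    sex = c("F", "M", "F"),
    nart_errors = c(12, 20, 8),
    mmse = c(29, 27, 30),
    stringsAsFactors = FALSE)
  set.seed(11)
  for (j in seq_along(sc)) df[[sc[j]]] <- round(stats::rnorm(3, 10 + j, 2), 1)
  df
}

write_tiny_cohort_csv <- function(df = tiny_cohort_df(),
                                  path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  path
}

# small standardized regression problem with a known conjugate posterior
conjugate_fixture <- function(n = 80, slope = 0.3, seed = 42) {
  set.seed(seed)
  x <- as.vector(scale(stats::rnorm(n)))
  y <- as.vector(scale(slope * x + stats::rnorm(n)))
  schema <- cognest:::single_outcome_schema("y")
  data <- structure(list(
    x = x, Y = matrix(y, ncol = 1, dimnames = list(NULL, "y")),
    C = matrix(numeric(0), n, 0), schema = schema, covariates = character(),
    scaling_record = data.frame(column = "y", center = 0, scale = 1,
                                inverted = FALSE),
    n = n), class = "analysis_matrix")
  data
}

# fast MCMC schedule for unit tests
quick_config <- function(seed = 1, n_chains = 3L) {
  mcmc_config(n_chains = n_chains, adapt_steps = 400L, burnin_steps = 800L,
              saved_samples_total = 1800L, thin = 2L, seed = seed,
              preset = "test")
}

# brute-force HDI: enumerate every window of ceil(mass*n) sorted samples
brute_hdi <- function(samples, mass) {
  s <- sort(samples)
  n <- length(s)
  k <- ceiling(mass * n)
  best <- c(s[1], s[min(k, n)])
  if (k >= n) return(best)
  for (i in seq_len(n - k + 1)) {
    w <- s[i + k - 1] - s[i]
    if (w < best[2] - best[1] - 1e-15) best <- c(s[i], s[i + k - 1])
  }
  best
}

# one shared test-preset fit of the default synthetic cohort, computed once
default_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_cohort(generator_config(seed = 5))
      am <- build_analysis_matrix(g$cohort)
      post <- run_mcmc(model_spec(), am, mcmc_config(preset = "test",
                                                     seed = 1))
      cache <<- list(gen = g, am = am, post = post)
    }
    cache
  }
})
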