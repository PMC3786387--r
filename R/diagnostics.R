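#' Highest density interval (shortest-interval estimator)
#'
#' Returns the narrowest interval containing `ceiling(mass * n)` of the
#' sorted samples.  Ties between equally narrow candidate windows are
#' broken by the lowest starting index (a fixed, documented convention that
#' matters only for discrete or heavily tied samples).
#'
#' @param samples Numeric vector of posterior draws (at least 20).
#' @param mass Probability mass of the interval, in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hdi(1:100, 0.95)   # c(1, 95)
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < 20L) stop("hdi needs at least 20 samples")
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  s <- sort(samples)
  n <- length(s)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = s[1], upper = s[n]))
  widths <- s[k:n] - s[1:(n - k + 1L)]
  i <- which.min(widths)   # which.min takes the first minimum: lowest start
  c(lower = s[i], upper = s[i + k - 1L])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic (non-split, no degrees-of-freedom correction) PSRF
#' `sqrt(((n-1)/n * W + B/n) / W)` from the between-chain variance `B` and
#' mean within-chain variance `W`.  A split-chain variant (each chain cut
#' in half and treated as two chains) is available via `split`.
#'
#' @param chains A numeric matrix, iterations x chains (at least 2 chains
#'   of equal length >= 10).
#' @param split Use the split-chain variant (default `FALSE`).
#' @return The PSRF (>= `sqrt((n-1)/n)`; approximately 1 at convergence).
#' @export
gelman_rubin <- function(chains, split = FALSE) {
  chains <- as.matrix(chains)
  if (split) {
    n2 <- floor(nrow(chains) / 2)
    chains <- cbind(chains[seq_len(n2), , drop = FALSE],
                    chains[nrow(chains) - n2 + seq_len(n2), , drop = FALSE])
  }
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2L) stop("gelman_rubin needs at least 2 chains")
  if (n < 10L) stop("chains must have at least 10 iterations")
  W <- mean(apply(chains, 2, stats::var))
  if (!is.finite(W) || W == 0) stop("degenerate chains (zero within-chain variance)")
  B <- n * stats::var(colMeans(chains))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' `N / (1 + 2 * sum(rho_t))`, with autocorrelations averaged across chains
#' (after centering each chain) and truncated by Geyer's initial positive
#' sequence rule: summation stops before the first non-positive sum of an
#' adjacent autocorrelation pair.  Capped at the total draw count.
#'
#' @param chains Iterations x chains matrix (a vector is treated as one
#'   chain).
#' @param max_lag Largest autocorrelation lag examined.
#' @return The effective sample size.
#' @export
effective_sample_size <- function(chains, max_lag = 2000L) {
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (n < 10L) stop("chains must have at least 10 iterations")
  v <- mean(apply(chains, 2, stats::var))
  if (!is.finite(v) || v == 0) stop("degenerate chains (zero variance)")
  lag_max <- min(max_lag, n - 2L)
  # average autocovariance across chains
  gamma_hat <- rowMeans(vapply(seq_len(m), function(ch) {
    a <- stats::acf(chains[, ch], lag.max = lag_max, type = "covariance",
                    plot = FALSE, demean = TRUE)
    as.vector(a$acf)
  }, numeric(lag_max + 1L)))
  rho <- gamma_hat / gamma_hat[1L]
  # Geyer initial positive sequence on pair sums rho[2t] + rho[2t+1]
  s <- 0
  t <- 1L
  while (t + 1L <= lag_max) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- (n * m) / (1 + 2 * s)
  min(ess, n * m)
}

#' Summarize posterior draws
#'
#' Posterior mean, SD, 80% and 95% highest-density intervals, Gelman-Rubin
#' PSRF and effective sample size for each requested parameter.  Derived
#' parameters are available by name: `theta[j]` (outcome-level slope),
#' `domain[d]` (domain-level slope) and `nu`.
#'
#' @param post A `posterior_samples` object from [run_mcmc()].
#' @param parameters Character vector of (raw or derived) parameter names.
#' @return An `mcmc_summary` data frame with columns `parameter`, `mean`,
#'   `sd`, `hdi80_lower`, `hdi80_upper`, `hdi95_lower`, `hdi95_upper`,
#'   `psrf`, `ess`.
#' @export
summarize_posterior <- function(post, parameters = c("beta",
                                                     paste0("domain[", 1:5, "]"))) {
  rows <- lapply(parameters, function(p) {
    cm <- derived_draws(post, p)      # chains x iterations
    pooled <- as.vector(t(cm))
    h80 <- hdi(pooled, 0.80)
    h95 <- hdi(pooled, 0.95)
    data.frame(parameter = p, mean = mean(pooled), sd = stats::sd(pooled),
               hdi80_lower = h80[["lower"]], hdi80_upper = h80[["upper"]],
               hdi95_lower = h95[["lower"]], hdi95_upper = h95[["upper"]],
               psrf = if (nrow(cm) >= 2) gelman_rubin(t(cm)) else NA_real_,
               ess = effective_sample_size(t(cm)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mcmc_summary", "data.frame")
  out
}

#' @export
print.mcmc_summary <- function(x, digits = 3, ...) {
  cat("Posterior summary (mean, 80%/95% HDI, PSRF, ESS):\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Export a posterior summary
#'
#' @param summary An `mcmc_summary`.
#' @param path Output path; format chosen by extension (`.tsv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(summary), path, digits = NA,
                         pretty = TRUE)
  } else {
    utils::write.table(as.data.frame(summary), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
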