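## Builders used across test files. Everything is generated in code.

## Weibull-kinetics series on a standard labeling design.
make_series <- function(a = 5, b = 0.01, p = 0.8, d = 0, sigma = 0.2,
                        times = c(0, 30, 300, 3600), R = 3, C = 2,
                        delta_a = 0, seed = 1) {
  set.seed(seed)
  df <- expand.grid(time_s = times, replicate = seq_len(R),
                    condition = paste0("C", seq_len(C)))
  df$peptide <- "pep1"
  a_c <- a + delta_a * (as.integer(factor(df$condition)) - 1)
  mu <- ifelse(df$time_s > 0,
               weibull_mean(df$time_s, a = 1, b = b, p = p) * a_c + d, d)
  df$uptake_da <- ifelse(df$time_s > 0,
                         stats::rnorm(nrow(df), mu, sigma), 0)
  df
}

quick_cfg <- function(seed = 1, chains = 2, warmup = 500, samples = 500)
  mcmc_config(chains = chains, warmup = warmup, samples = samples,
              seed = seed)

## conjugate Normal(mu, s2 known) with Normal prior on mu: closed-form
## evidence and exact posterior sampler
conj_normal <- function(y, s, m0, tau) {
  n <- length(y)
  vpost <- 1 / (n / s^2 + 1 / tau^2)
  mpost <- vpost * (sum(y) / s^2 + m0 / tau^2)
  Sig <- diag(s^2, n) + tau^2
  list(
    log_evidence = mvtnorm::dmvnorm(y, rep(m0, n), Sig, log = TRUE),
    rpost = function(S) matrix(stats::rnorm(S, mpost, sqrt(vpost)),
                               ncol = 1),
    log_unnorm = function(th) vapply(th[, 1], function(mu)
      sum(stats::dnorm(y, mu, s, log = TRUE)) +
        stats::dnorm(mu, m0, tau, log = TRUE), numeric(1)))
}
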