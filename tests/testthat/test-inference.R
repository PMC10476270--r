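test_that("fits are deterministic given the seed", {
  ser <- make_series(seed = 8)
  spec <- model_spec("weibull", "null")
  f1 <- suppressWarnings(fit_peptide(ser, spec, quick_cfg(seed = 5,
                                                          warmup = 300,
                                                          samples = 200)))
  f2 <- suppressWarnings(fit_peptide(ser, spec, quick_cfg(seed = 5,
                                                          warmup = 300,
                                                          samples = 200)))
  expect_identical(f1$draws_u, f2$draws_u)
  expect_identical(f1$loglik, f2$loglik)
  f3 <- suppressWarnings(fit_peptide(ser, spec, quick_cfg(seed = 6,
                                                          warmup = 300,
                                                          samples = 200)))
  expect_false(identical(f1$draws_u, f3$draws_u))
})

test_that("the sampler recovers the prior when the likelihood is disabled", {
  pr <- prior_hyper(a_loc = log(5))
  ser <- data.frame(peptide = "x", condition = "C1", replicate = 1,
                    time_s = c(0, 30, 300), uptake_da = c(0, 1, 2))
  f <- suppressWarnings(
    fit_peptide(ser, model_spec("weibull", "null", pr),
                mcmc_config(chains = 2, warmup = 1000, samples = 2000,
                            seed = 4), prior_only = TRUE))
  ## compare empirical CDFs against the analytic prior CDFs at fixed
  ## points (draws are autocorrelated, so use a distance, not a p-value)
  check_cdf <- function(x, cdf, tol = 0.05) {
    q <- seq(0.1, 0.9, by = 0.2)
    at <- quantile(x, q, names = FALSE)
    expect_lt(max(abs(cdf(at) - q)), tol)
  }
  check_cdf(f$draws[, "d"], function(z) pnorm(z, pr$d_loc, pr$d_scale))
  check_cdf(f$draws[, "a"], function(z) plnorm(z, pr$a_loc, pr$a_scale))
  check_cdf(f$draws[, "b"], function(z) plnorm(z, pr$b_loc, pr$b_scale))
  check_cdf(f$draws[, "sigma"], function(z) pexp(z, pr$sigma_rate))
})

test_that("per-observation log-likelihood matrix matches the data shape", {
  ser <- make_series(seed = 2)
  f <- suppressWarnings(fit_peptide(ser, model_spec("weibull", "alt"),
                                    quick_cfg(warmup = 300, samples = 150)))
  expect_equal(dim(f$loglik), c(2 * 150, nrow(ser)))
  expect_true(all(is.finite(f$loglik)))
  expect_true(all(is.finite(f$draws_u)))
  ## stored pointwise values agree with direct evaluation
  i <- 37
  pars <- hdxbayes:::.theta_to_params(f$mf, f$draws_u[i, ])
  ll <- log_likelihood(ser, pars, model_spec("weibull", "alt"))
  expect_equal(sum(f$loglik[i, ]), ll, tolerance = 1e-8)
})

test_that("rank-normalized split-Rhat is near 1 for iid draws and large for split chains", {
  set.seed(33)
  m_good <- matrix(rnorm(4000), ncol = 4)
  expect_lt(abs(hdxbayes:::.split_rhat(m_good) - 1), 0.01)
  m_bad <- cbind(rnorm(1000), rnorm(1000) + 5)
  rhat_bad <- hdxbayes:::.split_rhat(m_bad)
  expect_gt(rhat_bad, 1.5)
  ## agreement with an independent transcription of the formula
  split_cols <- cbind(m_bad[1:500, ], m_bad[501:1000, ])
  z <- qnorm((rank(split_cols) - 3 / 8) / (length(split_cols) + 1 / 4))
  zm <- matrix(z, nrow = 500)
  W <- mean(apply(zm, 2, var)); B <- 500 * var(colMeans(zm))
  expect_equal(rhat_bad, sqrt(499 / 500 + B / (W * 500)), tolerance = 1e-12)
})

test_that("diagnostics report Rhat, ESS and divergences per parameter", {
  ser <- make_series(seed = 13)
  f <- suppressWarnings(fit_peptide(ser, model_spec("logistic", "null"),
                                    quick_cfg(warmup = 400, samples = 300)))
  d <- diagnostics(f)
  expect_setequal(d$parameter, c("d", "a", "b", "sigma"))
  expect_true(all(d$ess <= length(f$chain) + 1e-9))
  expect_true(all(d$divergences >= 0))
  ## single chain: limited diagnostics, warned
  f1 <- suppressWarnings(fit_peptide(ser, model_spec("logistic", "null"),
                                     quick_cfg(chains = 1, warmup = 400,
                                               samples = 300)))
  expect_warning(diagnostics(f1), "single chain")
})

test_that("posterior for the plateau contracts as data double", {
  sds <- sapply(1:4, function(s) {
    f2 <- suppressWarnings(fit_peptide(
      make_series(R = 2, sigma = 0.3, seed = 100 + s),
      model_spec("weibull", "null"), quick_cfg(seed = s, warmup = 400,
                                               samples = 300)))
    f4 <- suppressWarnings(fit_peptide(
      make_series(R = 4, sigma = 0.3, seed = 100 + s),
      model_spec("weibull", "null"), quick_cfg(seed = s, warmup = 400,
                                               samples = 300)))
    c(sd(f2$draws[, "a"]), sd(f4$draws[, "a"]))
  })
  expect_lt(mean(sds[2, ]), mean(sds[1, ]))
})

test_that("flagging triggers on poor convergence", {
  ## two chains deliberately too short to mix on a hard posterior
  ser <- make_series(sigma = 0.02, seed = 3)
  expect_warning(
    fit_peptide(ser, model_spec("weibull", "alt"),
                mcmc_config(chains = 2, warmup = 100, samples = 100,
                            max_leapfrog = 2, seed = 1)),
    "flagged")
})
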