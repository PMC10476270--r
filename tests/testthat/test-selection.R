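test_that("bridge estimate matches the conjugate closed-form evidence", {
  skip_if_not_installed("mvtnorm")
  set.seed(14)
  cj <- conj_normal(y = rnorm(12, 1.2, 1.5), s = 1.5, m0 = 0.5, tau = 2)
  draws <- cj$rpost(4000)
  b <- bridge_log_marginal(draws, cj$log_unnorm, bridge_config())
  expect_true(b$converged)
  expect_lt(abs(b$logml - cj$log_evidence), 3 * max(b$mc_se, 2e-3))
})

test_that("an already-normalized target has log evidence zero", {
  set.seed(15)
  draws <- matrix(rnorm(4000), ncol = 1)
  b <- bridge_log_marginal(draws, function(x) dnorm(x[, 1], log = TRUE))
  expect_lt(abs(b$logml), 3 * max(b$mc_se, 2e-3))
})

test_that("scaling the unnormalized posterior shifts the evidence exactly", {
  set.seed(16)
  cj <- conj_normal(y = rnorm(8, 0, 1), s = 1, m0 = 0, tau = 1)
  draws <- cj$rpost(3000)
  run <- function(off) {
    set.seed(99)  # same proposal randomness for both runs
    bridge_log_marginal(draws, function(th) cj$log_unnorm(th) + off)$logml
  }
  expect_equal(run(7.3) - run(0), 7.3, tolerance = 1e-8)
})

test_that("bridge matches 2D grid quadrature on a two-parameter model", {
  ## y ~ N(mu, s2), conjugate normal-inverse-gamma prior; draws exact
  set.seed(17)
  n <- 15; y <- rnorm(n, 0.8, 1.3)
  m0 <- 0; k0 <- 1; a0 <- 2; b0 <- 2
  lup <- function(th) vapply(seq_len(nrow(th)), function(i) {
    mu <- th[i, 1]; ls <- th[i, 2]; s2 <- exp(2 * ls)
    sum(dnorm(y, mu, sqrt(s2), log = TRUE)) +
      dnorm(mu, m0, sqrt(s2 / k0), log = TRUE) +
      (a0 * log(b0) - lgamma(a0) - (a0 + 1) * log(s2) - b0 / s2) +
      log(2 * s2)            # Jacobian of s2 = exp(2 ls)
  }, numeric(1))
  ## closed form: marginal t evidence
  kn <- k0 + n; mn <- (k0 * m0 + sum(y)) / kn
  an <- a0 + n / 2
  bn <- b0 + 0.5 * (sum((y - mean(y))^2) +
                      k0 * n * (mean(y) - m0)^2 / kn)
  log_ev <- lgamma(an) - lgamma(a0) + a0 * log(b0) - an * log(bn) +
    0.5 * (log(k0) - log(kn)) - (n / 2) * log(2 * pi)
  ## independent check: trapezoid quadrature on a fine 2D grid
  mus <- seq(-1, 2.5, length.out = 401)
  lss <- seq(-1.2, 1.2, length.out = 401)
  grid <- as.matrix(expand.grid(mus, lss))
  lv <- matrix(lup(grid), length(mus))
  M <- max(lv)
  quad <- M + log(sum(exp(lv - M)) * diff(mus)[1] * diff(lss)[1])
  expect_equal(quad, log_ev, tolerance = 1e-3)
  ## exact posterior draws: s2 ~ IG(an, bn); mu | s2 ~ N(mn, s2/kn)
  s2d <- 1 / rgamma(4000, an, rate = bn)
  mud <- rnorm(4000, mn, sqrt(s2d / kn))
  draws <- cbind(mud, 0.5 * log(s2d))
  b <- bridge_log_marginal(draws, lup, bridge_config())
  expect_lt(abs(b$logml - quad), 1e-2)
})

test_that("bridge estimator variance decreases with more proposal draws", {
  set.seed(18)
  cj <- conj_normal(y = rnorm(10, 0.3, 1), s = 1, m0 = 0, tau = 1.5)
  sds <- sapply(c(50, 200, 800), function(n2) {
    ests <- sapply(1:24, function(r) {
      set.seed(1000 + r)
      draws <- cj$rpost(400)
      bridge_log_marginal(draws, cj$log_unnorm,
                          bridge_config(n_proposal = n2))$logml
    })
    sd(ests)
  })
  expect_true(all(diff(sds) < 0))
})

test_that("identical models give a Bayes factor of one within MC error", {
  ser <- make_series(seed = 19)
  spec <- model_spec("weibull", "null")
  e1 <- bridge_evidence(suppressWarnings(
    fit_peptide(ser, spec, quick_cfg(seed = 1))))
  e2 <- bridge_evidence(suppressWarnings(
    fit_peptide(ser, spec, quick_cfg(seed = 2))))
  expect_lt(abs(e1$logml - e2$logml),
            4 * sqrt(e1$mc_se^2 + e2$mc_se^2) + 0.05)
})

test_that("bayes_factor and posterior_model_prob satisfy their identities", {
  expect_equal(bayes_factor(1, 1)$bf, 1)
  expect_equal(bayes_factor(2, 1)$bf, exp(1))
  b <- bayes_factor(-3.2, 1.7)
  expect_equal(b$bf, 1 / bayes_factor(1.7, -3.2)$bf)
  expect_equal(posterior_model_prob(1, prior_odds = 1), 0.5)
  expect_equal(posterior_model_prob(3, prior_odds = 1), 0.75)
  expect_equal(posterior_model_prob(1, prior_odds = 3), 0.25)
  ## increasing the prior odds of the null strictly lowers P(M1|D)
  p <- sapply(c(0.5, 1, 3, 10), posterior_model_prob, bf = 2)
  expect_true(all(diff(p) < 0))
  ## posterior odds = prior odds^-1 * BF consistency
  pr <- posterior_model_prob(log_bf = 2.4, prior_odds = 3)
  expect_equal(pr / (1 - pr), exp(2.4) / 3, tolerance = 1e-12)
})

test_that("test_peptide detects a plateau shift and not its absence", {
  ## strong effect: plateau differs by ~6 noise SDs
  ser_eff <- make_series(delta_a = 1.8, sigma = 0.3, seed = 21)
  r_eff <- suppressWarnings(test_peptide(ser_eff, cfg = quick_cfg(seed = 3)))
  expect_gt(r_eff$prob_alt, 0.95)
  ## no effect
  ser_null <- make_series(delta_a = 0, sigma = 0.3, seed = 22)
  r_null <- suppressWarnings(test_peptide(ser_null, cfg = quick_cfg(seed = 3)))
  expect_lt(r_null$prob_alt, 0.5)
  ## invariants of the result row
  for (r in list(r_eff, r_null)) {
    expect_true(r$prob_alt >= 0 && r$prob_alt <= 1)
    ## posterior odds = prior odds of alt (1/prior_odds) times BF
    expect_equal(r$post_odds, r$bf / r$prior_odds, tolerance = 1e-12)
    expect_equal(r$prob_alt / (1 - r$prob_alt), r$post_odds,
                 tolerance = 1e-6)
  }
  expect_error(test_peptide(make_series(C = 1)), "2 conditions")
})

test_that("test_all_peptides reports failures without dropping peptides", {
  sim <- simulate_dataset(sim_config("A", n_peptides = 2, seed = 23))
  nd <- normalize_uptake(sim$data)
  ## poison one peptide with a non-finite uptake value
  nd$uptake_da[nd$peptide == "pep002"][1] <- NA
  res <- suppressWarnings(
    test_all_peptides(nd, cfg = quick_cfg(warmup = 300, samples = 200)))
  expect_equal(nrow(res), 1)
  expect_match(names(attr(res, "failed")), "pep002")
})
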