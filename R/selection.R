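#' Bridge sampling configuration
#'
#' @param n_proposal number of proposal draws `n2` (default: as many as
#'   the estimation half of the posterior sample).
#' @param tol relative convergence tolerance of the iterative estimator.
#' @param max_iter maximum number of iterations.
#' @param split fraction of posterior draws used for proposal moment
#'   matching; the remainder is used for estimation (avoids reuse bias).
#' @return an object of class `hdx_bridge_config`.
#' @export
bridge_config <- function(n_proposal = NULL, tol = 1e-10, max_iter = 1000,
                          split = 0.5) {
  stopifnot(is.null(n_proposal) || n_proposal > 0, tol > 0, max_iter >= 1,
            split > 0, split < 1)
  structure(list(n_proposal = n_proposal, tol = tol,
                 max_iter = as.integer(max_iter), split = split),
            class = "hdx_bridge_config")
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## multivariate normal log density given the Cholesky factor of the
## covariance (upper triangular, as returned by chol())
.dmvnorm_chol <- function(x, mean, chol_up, log_det) {
  z <- backsolve(chol_up, t(x) - mean, transpose = TRUE)
  -0.5 * (ncol(x) * log(2 * pi) + log_det + colSums(z^2))
}

#' Log marginal likelihood by iterative optimal bridge sampling
#'
#' Estimates `log p(D)` from posterior draws and evaluations of the
#' unnormalized log posterior. The posterior sample is split: one part
#' fixes the moments of a Gaussian proposal on the unconstrained scale,
#' the other enters the estimator, so that no draw is reused. The optimal
#' bridge function (minimum relative mean-squared error) is used, with
#' the implied fixed-point iteration
#' \deqn{\hat r^{(t+1)} = \frac{\frac{1}{n_2}\sum_j \ell_{2j} /
#'   (s_1 \ell_{2j} + s_2 \hat r^{(t)})}{\frac{1}{n_1}\sum_i 1 /
#'   (s_1 \ell_{1i} + s_2 \hat r^{(t)})}}
#' where \eqn{\ell = q(\theta)/g(\theta)} are unnormalized posterior to
#' proposal ratios at proposal (`2`) and posterior (`1`) draws, and
#' \eqn{s_1 = n_1/(n_1+n_2)}, \eqn{s_2 = n_2/(n_1+n_2)}. All arithmetic
#' is in log space; the iteration starts from the reciprocal importance
#' sampling estimate. An approximate Monte-Carlo standard error of the
#' log evidence is returned (spectral-density correction for the
#' autocorrelated posterior part).
#'
#' @param draws_u matrix of posterior draws on the unconstrained scale
#'   (rows = draws).
#' @param log_unnorm_posterior function taking a matrix of points (rows)
#'   and returning the unnormalized log posterior density at each row.
#' @param cfg a [bridge_config()].
#' @return list with `logml`, `mc_se`, `niter`, `converged`, `n1`, `n2`.
#' @export
bridge_log_marginal <- function(draws_u, log_unnorm_posterior,
                                cfg = bridge_config()) {
  stopifnot(is.matrix(draws_u), nrow(draws_u) >= 20)
  S <- nrow(draws_u); dim <- ncol(draws_u)

  ## interleaved split balances chains stacked in order
  idx_fit <- seq(1, S, by = round(1 / cfg$split))
  idx_est <- setdiff(seq_len(S), idx_fit)
  fit_half <- draws_u[idx_fit, , drop = FALSE]
  est_half <- draws_u[idx_est, , drop = FALSE]
  n1 <- nrow(est_half)
  n2 <- if (is.null(cfg$n_proposal)) n1 else as.integer(cfg$n_proposal)

  m <- colMeans(fit_half)
  V <- stats::cov(fit_half)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    ## degenerate covariance: retry with a diagonal + jitter fallback
    V <- diag(pmax(apply(fit_half, 2, stats::var), 1e-10), dim)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch))
      stop("degenerate posterior covariance; consider jittering draws")
  }
  log_det <- 2 * sum(log(diag(ch)))

  prop <- matrix(stats::rnorm(n2 * dim), n2, dim) %*% ch +
    matrix(m, n2, dim, byrow = TRUE)
  colnames(prop) <- colnames(draws_u)

  ## log ratios l = log q - log g at posterior (l1) and proposal (l2) draws
  l1 <- log_unnorm_posterior(est_half) - .dmvnorm_chol(est_half, m, ch, log_det)
  l2 <- log_unnorm_posterior(prop) - .dmvnorm_chol(prop, m, ch, log_det)
  if (any(!is.finite(l1)))
    stop("non-finite log posterior at posterior draws")
  keep <- is.finite(l2)          # proposal may land outside the support
  l2 <- l2[keep]
  n2_eff <- length(l2)
  if (n2_eff < 10) stop("almost all proposal draws fell outside the support")

  s1 <- n1 / (n1 + n2_eff)
  s2 <- n2_eff / (n1 + n2_eff)
  lstar <- stats::median(l1)

  ## reciprocal-importance initial guess (on the exp(lstar) shifted scale)
  r <- exp(.logsumexp(l2) - log(n2_eff) - lstar)
  converged <- FALSE
  niter <- 0L
  f1 <- f2 <- NULL
  for (it in seq_len(cfg$max_iter)) {
    niter <- it
    f1 <- 1 / (s1 + s2 * r * exp(lstar - l2))   # proposal-side terms
    f2 <- 1 / (s1 * exp(l1 - lstar) + s2 * r)   # posterior-side terms
    r_new <- mean(f1) / mean(f2)
    if (!is.finite(r_new) || r_new <= 0)
      stop("bridge iteration diverged (r = ", r_new, ") at iteration ", it)
    if (abs(r_new - r) / r_new < cfg$tol) {
      r <- r_new; converged <- TRUE; break
    }
    r <- r_new
  }
  if (!converged)
    stop("bridge sampling did not converge within ", cfg$max_iter,
         " iterations (last relative change at r = ", signif(r, 6), ")")

  ## approximate relative MSE (Fruehwirth-Schnatter 2004 style): i.i.d.
  ## proposal part + spectral-density-corrected posterior part
  vf1 <- stats::var(f1) / (n2_eff * mean(f1)^2)
  rho0 <- tryCatch(coda::spectrum0.ar(f2)$spec / stats::var(f2),
                   error = function(e) 1)
  if (!is.finite(rho0) || rho0 <= 0) rho0 <- 1
  vf2 <- rho0 * stats::var(f2) / (n1 * mean(f2)^2)
  mc_se <- sqrt(vf1 + vf2)

  list(logml = log(r) + lstar, mc_se = mc_se, niter = niter,
       converged = converged, n1 = n1, n2 = n2_eff)
}

#' Bridge-sampled log marginal likelihood of a fitted model
#'
#' Convenience wrapper applying [bridge_log_marginal()] to a
#' [fit_peptide()] result, using the fit's own unnormalized posterior
#' (likelihood + prior + transform Jacobian) on the unconstrained scale.
#'
#' @param fit an [fit_peptide()] result.
#' @param cfg a [bridge_config()].
#' @return as [bridge_log_marginal()].
#' @export
bridge_evidence <- function(fit, cfg = bridge_config()) {
  stopifnot(inherits(fit, "hdx_fit"))
  cm <- .cpp_model(fit$mf, prior_only = fit$prior_only)
  bridge_log_marginal(fit$draws_u,
                      function(x) cpp_lp_many(cm, x), cfg)
}

#' Bayes factor from two log marginal likelihoods
#'
#' @param log_ml1,log_ml0 log evidences of the alternative and null model.
#' @return list with `log_bf` and `bf` (`BF10`).
#' @export
bayes_factor <- function(log_ml1, log_ml0) {
  stopifnot(is.finite(log_ml1), is.finite(log_ml0))
  lbf <- log_ml1 - log_ml0
  list(log_bf = lbf, bf = exp(lbf))
}

#' Posterior model probability from a Bayes factor and prior odds
#'
#' Posterior odds are prior odds times the Bayes factor; the posterior
#' probability of the alternative follows as
#' `P(M1|D) = BF10 / (BF10 + prior_odds)` with
#' `prior_odds = pi0 / pi1`. The default prior favors the null
#' (`pi0 = 0.75`), an explicit multiplicity control.
#'
#' @param bf Bayes factor `BF10` (alternative over null), or its log via
#'   `log_bf` (numerically safer for extreme values).
#' @param prior_odds prior odds `pi0 / pi1` of null over alternative.
#' @param log_bf optional log Bayes factor, used if `bf` is missing.
#' @return posterior probability of the alternative model, in `[0, 1]`.
#' @export
posterior_model_prob <- function(bf, prior_odds = 3, log_bf = NULL) {
  stopifnot(prior_odds > 0)
  if (is.null(log_bf)) {
    stopifnot(bf > 0)
    log_bf <- log(bf)
  }
  ## P = BF/(BF + odds) = 1/(1 + exp(log odds - log BF))
  stats::plogis(log_bf - log(prior_odds))
}

#' Test one peptide for a condition effect
#'
#' Fits the context-blind (null) and context-specific (alternative)
#' versions of the chosen kinetic family to one peptide's uptake series,
#' estimates both marginal likelihoods by bridge sampling, and combines
#' them with the prior model odds into the posterior probability that the
#' kinetics depend on the condition. Both models share identical prior
#' hyperparameters (derived once from the pooled series when `prior` is
#' `NULL`) so that the Bayes factor compares structures, not priors.
#'
#' @param series normalized uptake series of one peptide with >= 2
#'   conditions.
#' @param family kinetic family passed to [model_spec()].
#' @param prior optional [prior_hyper()]; default derives one from the
#'   pooled series via [auto_prior()].
#' @param cfg an [mcmc_config()]; the null fit uses `cfg$seed` and the
#'   alternative fit `cfg$seed + 1`.
#' @param bridge a [bridge_config()].
#' @param prior_odds prior odds `pi0/pi1` of null over alternative.
#' @param keep_fits if `TRUE` the two `hdx_fit` objects are attached.
#' @return an object of class `hdx_test`: a one-row data frame with
#'   `peptide`, `logml_null`, `logml_alt`, `log_bf`, `bf`, `prior_odds`,
#'   `post_odds`, `prob_alt`, `mc_se`, `flags`.
#' @export
test_peptide <- function(series, family = "weibull", prior = NULL,
                         cfg = mcmc_config(), bridge = bridge_config(),
                         prior_odds = 3, keep_fits = FALSE) {
  if (length(unique(series$condition)) < 2)
    stop("test_peptide requires at least 2 conditions for peptide '",
         series$peptide[1], "'")
  if (is.null(prior)) prior <- auto_prior(series)
  pep <- as.character(series$peptide[1])

  run <- function(structure, seed_off) {
    spec <- model_spec(family, structure, prior)
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + seed_off
    fit <- withCallingHandlers(
      fit_peptide(series, spec, cfg_i),
      warning = function(w) invokeRestart("muffleWarning"))
    ev <- tryCatch(bridge_evidence(fit, bridge), error = function(e)
      stop("bridge sampling failed for peptide '", pep, "' (",
           structure, " model): ", conditionMessage(e), call. = FALSE))
    list(fit = fit, ev = ev)
  }
  m0 <- run("null", 0L)
  m1 <- run("alt", 1L)

  bf <- bayes_factor(m1$ev$logml, m0$ev$logml)
  prob <- posterior_model_prob(log_bf = bf$log_bf, prior_odds = prior_odds)
  flags <- paste(c(if (m0$fit$flagged) "null_fit",
                   if (m1$fit$flagged) "alt_fit"), collapse = ";")
  out <- data.frame(
    peptide = pep,
    logml_null = m0$ev$logml, logml_alt = m1$ev$logml,
    log_bf = bf$log_bf, bf = bf$bf,
    prior_odds = prior_odds,
    post_odds = bf$bf / prior_odds,
    prob_alt = prob,
    mc_se = sqrt(m0$ev$mc_se^2 + m1$ev$mc_se^2),
    flags = flags, stringsAsFactors = FALSE)
  class(out) <- c("hdx_test", class(out))
  if (keep_fits) {
    attr(out, "fit_null") <- m0$fit
    attr(out, "fit_alt") <- m1$fit
  }
  out
}

#' Test every peptide in a normalized uptake table
#'
#' Applies [test_peptide()] to each peptide. Peptides whose fit or bridge
#' estimate fails are reported in the `failed` attribute with their error
#' message rather than dropped silently.
#'
#' @param data normalized uptake table (several peptides).
#' @param ... passed to [test_peptide()].
#' @param verbose print one line per peptide.
#' @return data frame with one row per successfully tested peptide; the
#'   `failed` attribute is a named character vector of error messages.
#' @export
test_all_peptides <- function(data, ..., verbose = FALSE) {
  ids <- unique(as.character(data$peptide))
  res <- vector("list", length(ids))
  failed <- character(0)
  for (i in seq_along(ids)) {
    ser <- data[data$peptide == ids[i], , drop = FALSE]
    t0 <- Sys.time()
    r <- tryCatch(test_peptide(ser, ...), error = function(e)
      conditionMessage(e))
    if (is.character(r)) {
      failed[ids[i]] <- r
      if (verbose) message(ids[i], ": FAILED (", r, ")")
    } else {
      res[[i]] <- r
      if (verbose)
        message(sprintf("%s: prob_alt = %.3f [%.1fs]", ids[i], r$prob_alt,
                        as.numeric(Sys.time() - t0, units = "secs")))
    }
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  attr(out, "failed") <- failed
  out
}
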