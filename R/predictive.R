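#' Prior predictive ensemble
#'
#' Simulates datasets on a given design by drawing parameters from the
#' prior and then data from the Gaussian observation model around the
#' kinetic mean curve.
#'
#' @param spec a [model_spec()] with an explicit prior.
#' @param design data frame with `time_s`, `condition` (and `replicate`
#'   for the random-effects family) describing the observation grid.
#' @param n number of simulated datasets.
#' @return an object of class `hdx_ensemble`: matrix `y` (`n` rows, one
#'   column per design row), the design, and `source = "prior"`.
#' @export
prior_predictive <- function(spec, design, n = 100) {
  stopifnot(inherits(spec, "hdx_model_spec"), n >= 1)
  if (is.null(spec$prior))
    stop("prior_predictive needs a model_spec with an explicit prior")
  conds <- sort(unique(as.character(design$condition)))
  nb <- if (spec$structure == "alt") length(conds) else 1L
  re <- spec$family == "weibull_re"
  grp_key <- if (re) paste(design$condition, design$replicate, sep = ".")
  grp_lev <- if (re) unique(grp_key)
  y <- matrix(NA_real_, n, nrow(design))
  params <- vector("list", n)
  for (s in seq_len(n)) {
    blocks <- sample_prior(spec$prior, spec$family, n = nb)
    bi <- if (spec$structure == "alt")
      match(as.character(design$condition), conds) else rep(1L, nrow(design))
    a_eff <- blocks$a[bi]
    if (re) {
      u <- stats::rnorm(length(grp_lev), 0, blocks$tau[1])
      a_eff <- a_eff + u[match(grp_key, grp_lev)]
    }
    mu <- .mean_curve(spec$family, design$time_s, a_eff, blocks$b[bi],
                      if (!is.null(blocks$p)) blocks$p[bi], blocks$d[bi])
    y[s, ] <- stats::rnorm(nrow(design), mu, blocks$sigma[bi])
    params[[s]] <- blocks
  }
  structure(list(y = y, design = design, source = "prior",
                 params = params),
            class = "hdx_ensemble")
}

.mean_curve <- function(family, t, a, b, p, d) {
  if (family == "logistic") {
    s <- ifelse(t > 0, stats::plogis(b * log(t)), 0)
    d + a * s
  } else {
    g <- ifelse(t > 0, -expm1(-(b * t)^p), 0)
    d + a * g
  }
}

#' Posterior predictive ensemble
#'
#' Simulates datasets by drawing posterior parameter draws (with
#' replacement) and then data from the likelihood, on the fitted design
#' or a new one.
#'
#' @param fit an [fit_peptide()] result.
#' @param design observation grid; defaults to the fitted series design.
#' @param n number of simulated datasets.
#' @return an `hdx_ensemble` with `source = "posterior"`.
#' @export
posterior_predictive <- function(fit, design = NULL, n = 100) {
  stopifnot(inherits(fit, "hdx_fit"), n >= 1)
  mf <- fit$mf
  if (is.null(design))
    design <- data.frame(time_s = mf$t,
                         condition = mf$cond_levels[mf$cond],
                         replicate = mf$series$replicate)
  conds <- mf$cond_levels
  bi <- if (mf$spec$structure == "alt") {
    m <- match(as.character(design$condition), conds)
    if (any(is.na(m))) stop("design contains unknown condition label(s)")
    m
  } else rep(1L, nrow(design))
  rows <- sample.int(nrow(fit$draws_u), n, replace = TRUE)
  y <- matrix(NA_real_, n, nrow(design))
  for (s in seq_len(n)) {
    th <- fit$draws_u[rows[s], ]
    pars <- .theta_to_params(mf, th)
    a_eff <- pars$a[bi]
    if (mf$re) {
      ## reuse fitted group offsets where the design matches; new groups
      ## get fresh offsets from the posterior draw of tau
      grp_key <- paste(match(as.character(design$condition), conds),
                       design$replicate, sep = ".")
      known <- match(grp_key, unique(paste(mf$cond, mf$series$replicate,
                                           sep = ".")))
      u <- ifelse(is.na(known), stats::rnorm(length(grp_key), 0, pars$tau),
                  pars$u[known])
      a_eff <- a_eff + u
    }
    mu <- .mean_curve(if (mf$family == "logistic") "logistic" else "weibull",
                      design$time_s, a_eff, pars$b[bi],
                      if (!is.null(pars$p)) pars$p[bi], pars$d[bi])
    y[s, ] <- stats::rnorm(nrow(design), mu, pars$sigma[bi])
  }
  structure(list(y = y, design = design, source = "posterior"),
            class = "hdx_ensemble")
}

#' Predictive-check summary of an ensemble against observed data
#'
#' Applies a summary statistic to every simulated dataset and to the
#' observed data, and reports the observed statistic's rank within the
#' ensemble together with a two-sided tail probability. A statistic that
#' is constant across the ensemble has no defined rank and is flagged
#' degenerate.
#'
#' @param ensemble an `hdx_ensemble`.
#' @param observed observed data vector on the ensemble design (or a
#'   series data frame with `uptake_da`).
#' @param statistic function of a data vector (given the design as the
#'   second argument if it accepts one); default: mean.
#' @return list with `stat_obs`, `stat_sim`, `rank`, `tail_prob`,
#'   `degenerate`.
#' @export
ppc_summary <- function(ensemble, observed, statistic = mean) {
  stopifnot(inherits(ensemble, "hdx_ensemble"))
  if (is.data.frame(observed)) observed <- observed$uptake_da
  if (length(observed) != ncol(ensemble$y))
    stop("observed data does not match the ensemble design")
  fmls <- tryCatch(formals(statistic), error = function(e) NULL)
  takes_design <- length(fmls) >= 2 && names(fmls)[2] != "..."
  apply_stat <- function(v) {
    if (takes_design) statistic(v, ensemble$design) else statistic(v)
  }
  s_sim <- apply(ensemble$y, 1, apply_stat)
  s_obs <- apply_stat(observed)
  n <- length(s_sim)
  degenerate <- stats::var(s_sim) == 0 || !is.finite(stats::var(s_sim))
  if (degenerate)
    warning("summary statistic is constant across the ensemble; ",
            "rank undefined", call. = FALSE)
  p_le <- (1 + sum(s_sim <= s_obs)) / (n + 1)
  p_ge <- (1 + sum(s_sim >= s_obs)) / (n + 1)
  list(stat_obs = s_obs, stat_sim = s_sim,
       rank = sum(s_sim < s_obs) + 1L,
       tail_prob = min(1, 2 * min(p_le, p_ge)),
       degenerate = degenerate)
}

## ---- PSIS-LOO --------------------------------------------------------------

## Generalized Pareto fit to exceedances (profile-likelihood method of
## Zhang & Stephens 2009, as used in Pareto-smoothed importance sampling).
.gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  k_of <- function(th) -mean(log1p(-th * x))
  l_theta <- vapply(theta, function(th) {
    k <- k_of(th)
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m), function(j)
    sum(exp(l_theta - l_theta[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k_hat <- k_of(theta_hat)
  sigma_hat <- k_hat / theta_hat
  ## weakly informative bias correction toward k = 0.5 (standard recipe)
  k_hat <- (n * k_hat + 5) / (n + 10)
  list(k = k_hat, sigma = sigma_hat)
}

.qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Estimates the expected log pointwise predictive density under
#' leave-one-out cross-validation from a matrix of per-observation
#' log-likelihood values over posterior draws. The raw importance ratios
#' `1 / p(y_i | theta_s)` have their largest
#' `M = min(0.2 S, 3 sqrt(S))` values replaced by expected order
#' statistics of a generalized Pareto distribution fitted to that tail,
#' truncated at the largest raw ratio. Observations with a tail-shape
#' estimate `k > 0.7` are flagged as unreliable.
#'
#' @param loglik matrix of log-likelihood values, draws in rows,
#'   observations in columns.
#' @return an object of class `hdx_loo`: `elpd_loo`, `pointwise`,
#'   `khat`, `flagged` (which observations have `k > 0.7`).
#' @export
psis_loo <- function(loglik) {
  if (inherits(loglik, "hdx_fit")) loglik <- loglik$loglik
  stopifnot(is.matrix(loglik), all(is.finite(loglik)))
  S <- nrow(loglik); n_obs <- ncol(loglik)
  if (S < 100)
    warning("fewer than 100 draws; PSIS-LOO estimates will be noisy",
            call. = FALSE)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  pointwise <- numeric(n_obs)
  khat <- numeric(n_obs)
  for (i in seq_len(n_obs)) {
    ll <- loglik[, i]
    lw <- -ll                       # log raw importance ratios (up to const)
    lw <- lw - max(lw)
    if (stats::var(lw) == 0) {
      khat[i] <- NA_real_
      pointwise[i] <- ll[1]
      next
    }
    if (M >= 5) {
      ord <- order(lw)
      tail_ids <- ord[(S - M + 1):S]
      cut <- lw[ord[S - M]]
      exceed <- exp(lw[tail_ids]) - exp(cut)
      if (all(exceed > 0)) {
        fit <- .gpd_fit(exceed)
        khat[i] <- fit$k
        q <- vapply((seq_len(M) - 0.5) / M, .qgpd, numeric(1),
                    k = fit$k, sigma = fit$sigma)
        sm <- log(exp(cut) + q)
        sm <- pmin(sm, max(lw))     # truncate at the largest raw ratio
        lw[tail_ids[order(lw[tail_ids])]] <- sm
      } else khat[i] <- NA_real_
    } else khat[i] <- NA_real_
    lw <- lw - .logsumexp(lw)       # normalized log weights
    pointwise[i] <- .logsumexp(lw + ll)
  }
  flagged <- which(!is.na(khat) & khat > 0.7)
  if (length(flagged))
    warning(length(flagged), " observation(s) with Pareto k > 0.7; ",
            "PSIS-LOO may be unreliable for them", call. = FALSE)
  structure(list(elpd_loo = sum(pointwise), pointwise = pointwise,
                 khat = khat, flagged = flagged),
            class = "hdx_loo")
}

#' @export
print.hdx_loo <- function(x, ...) {
  cat("<hdx_loo> elpd_loo =", format(x$elpd_loo, digits = 6),
      "over", length(x$pointwise), "observations;",
      length(x$flagged), "with k > 0.7\n")
  invisible(x)
}
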