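#' Kinetic mean functions, priors and model structures
#'
#' @description
#' Deuterium uptake curves are modelled with smooth parametric saturation
#' kinetics. Two families are available:
#'
#' * **logistic**: \eqn{\mu(t) = d + a / (1 + \exp(-b \log t))}, with
#'   \eqn{\mu(0) = d} by continuity.
#' * **weibull**: \eqn{\mu(t) = d + a (1 - \exp(-(b t)^p))}.
#'
#' In both cases `d` is the intercept at time zero, `a` the plateau
#' amplitude (the curve is bounded in `[d, d + a]` for positive
#' parameters), `b` a rate/shape parameter and, for the Weibull family,
#' `p` a stretching exponent (`p = 1` recovers exponential saturation).
#' Observations are the mean plus Gaussian noise with standard deviation
#' `sigma`. The random-effects Weibull family (`"weibull_re"`) adds
#' replicate-level plateau offsets `u[c, r] ~ Normal(0, tau)` nested
#' within condition, so the plateau for condition `c`, replicate `r` is
#' `a[c] + u[c, r]`.
#'
#' A *null* structure shares one parameter block across all conditions
#' (context-blind); an *alternative* structure gives every condition its
#' own block (including its own `sigma`).
#'
#' @name hdx-models
NULL

.FAMILIES <- c("logistic", "weibull", "weibull_re")

#' Logistic uptake mean function
#'
#' @param t exposure time in seconds (vector, `t >= 0`).
#' @param a plateau amplitude, `a > 0`.
#' @param b shape/rate parameter, `b > 0`.
#' @param d intercept at `t = 0`.
#' @return expected uptake at each time.
#' @examples
#' logistic_mean(1, a = 2, b = 1, d = 0)   # half plateau: log(1) = 0
#' @export
logistic_mean <- function(t, a, b, d = 0) {
  stopifnot(all(t >= 0), a > 0, b > 0)
  s <- ifelse(t > 0, stats::plogis(b * log(t)), 0)
  d + a * s
}

#' Weibull uptake mean function
#'
#' @inheritParams logistic_mean
#' @param p Weibull exponent, `p > 0`; `p = 1` gives exponential
#'   saturation `d + a (1 - exp(-b t))`.
#' @return expected uptake at each time.
#' @examples
#' weibull_mean(2, a = 1, b = 0.5, p = 1, d = 0)  # 1 - exp(-1)
#' @export
weibull_mean <- function(t, a, b, p = 1, d = 0) {
  stopifnot(all(t >= 0), a > 0, b > 0, p > 0)
  g <- ifelse(t > 0, -expm1(-(b * t)^p), 0)
  d + a * g
}

#' Prior hyperparameters
#'
#' Hierarchical prior used for all model families:
#' \itemize{
#'   \item `d ~ Normal(d_loc, d_scale)` — symmetric, concentrated near 0;
#'   \item `a ~ LogNormal(a_loc, a_scale)` — positive plateau;
#'   \item `b ~ LogNormal(b_loc, b_scale)` — positive rate; the default
#'     location/scale make the prior half-saturation time `1/b` span the
#'     typical continuous-labeling window (tens of seconds to hours), as
#'     judged by prior predictive curves;
#'   \item `p ~ LogNormal(p_loc, p_scale)` — positive Weibull exponent,
#'     centered below 1 (stretched kinetics from superposed amide rates);
#'   \item `sigma ~ Exponential(sigma_rate)` — shrunk toward 0 so that the
#'     fit is not explained away as noise;
#'   \item `tau ~ half-Normal(0, tau_scale)` — random-plateau spread.
#' }
#' `auto_prior()` fills the data-scale dependent entries (`a_loc`,
#' `b_loc`, `sigma_rate`, `tau_scale`) from an uptake series.
#'
#' @param d_loc,d_scale location and scale of the intercept prior.
#' @param a_loc,a_scale log-scale location and scale of the plateau prior.
#' @param b_loc,b_scale log-scale location and scale of the rate prior.
#' @param p_loc,p_scale log-scale location and scale of the exponent
#'   prior.
#' @param sigma_rate rate of the exponential prior on the noise SD.
#' @param tau_scale scale of the half-normal prior on `tau`.
#' @return an object of class `hdx_prior`.
#' @export
prior_hyper <- function(d_loc = 0, d_scale = 0.5,
                        a_loc = log(5), a_scale = 0.75,
                        b_loc = log(1 / 300), b_scale = 2.5,
                        p_loc = log(0.6), p_scale = 0.8,
                        sigma_rate = 2,
                        tau_scale = 1) {
  h <- list(d_loc = d_loc, d_scale = d_scale, a_loc = a_loc,
            a_scale = a_scale, b_loc = b_loc, b_scale = b_scale,
            p_loc = p_loc, p_scale = p_scale, sigma_rate = sigma_rate,
            tau_scale = tau_scale)
  sc <- h[c("d_scale", "a_scale", "b_scale", "p_scale", "sigma_rate",
            "tau_scale")]
  if (!all(vapply(sc, function(x) is.finite(x) && x > 0, logical(1))))
    stop("all prior scale/rate hyperparameters must be positive")
  if (!all(vapply(h, is.finite, logical(1))))
    stop("prior hyperparameters must be finite")
  structure(h, class = "hdx_prior")
}

#' @rdname prior_hyper
#' @param series an uptake series (data frame with an `uptake_da` column).
#' @param ... overrides passed on to [prior_hyper()].
#' @details `auto_prior()` sets `a_loc = log(max uptake)` (plateau on the
#'   data scale), `b_loc = -log(median positive exposure time)` (prior
#'   half-saturation inside the observed window), `sigma_rate =
#'   1 / (0.1 * sd(uptake))` (prior mean one tenth of the data spread)
#'   and `tau_scale = 0.25 * max uptake`, with conservative fallbacks for
#'   degenerate series.
#' @export
auto_prior <- function(series, ...) {
  u <- series$uptake_da
  if (is.null(u) || !any(is.finite(u)))
    stop("series has no finite 'uptake_da' values; normalize first")
  umax <- max(u, na.rm = TRUE)
  usd <- stats::sd(u, na.rm = TRUE)
  tpos <- series$time_s[series$time_s > 0]
  tmid <- if (length(tpos)) stats::median(tpos) else 300
  if (!is.finite(umax) || umax <= 0) umax <- 1
  if (!is.finite(usd) || usd <= 0) usd <- 1
  prior_hyper(a_loc = log(umax), b_loc = -log(tmid),
              sigma_rate = 1 / (0.1 * usd),
              tau_scale = 0.25 * umax, ...)
}

#' Model specification
#'
#' @param family `"logistic"`, `"weibull"` or `"weibull_re"`.
#' @param structure `"null"` (one parameter block shared across
#'   conditions) or `"alt"` (condition-specific blocks).
#' @param prior an [prior_hyper()] object, or `NULL` to derive one from
#'   the data at fit time via [auto_prior()].
#' @return an object of class `hdx_model_spec`.
#' @export
model_spec <- function(family = c("weibull", "logistic", "weibull_re"),
                       structure = c("null", "alt"),
                       prior = NULL) {
  family <- match.arg(family)
  structure <- match.arg(structure)
  if (!is.null(prior) && !inherits(prior, "hdx_prior"))
    stop("'prior' must be built with prior_hyper()")
  structure(list(family = family, structure = structure, prior = prior),
            class = "hdx_model_spec")
}

#' @export
print.hdx_model_spec <- function(x, ...) {
  cat("<hdx_model_spec>", x$family,
      if (x$structure == "null") "(context-blind)" else "(context-specific)",
      "\n")
  invisible(x)
}

## ---- parameter bookkeeping -------------------------------------------------

## A "model frame" binds a spec to one peptide's data: observation vectors,
## condition / replicate-group indexing, the unconstrained parameter layout,
## and closures for the log posterior and its analytic gradient.
.model_frame <- function(series, spec) {
  if (is.null(series$uptake_da) || any(!is.finite(series$uptake_da)))
    stop("series must carry finite 'uptake_da' values (normalize first)")
  if (is.null(series$time_s) || any(series$time_s < 0))
    stop("series must carry nonnegative 'time_s'")
  y <- as.numeric(series$uptake_da)
  t <- as.numeric(series$time_s)
  cond_lev <- sort(unique(as.character(series$condition)))
  C <- length(cond_lev)
  cond <- match(as.character(series$condition), cond_lev)
  prior <- if (is.null(spec$prior)) auto_prior(series) else spec$prior
  fam <- spec$family
  nb <- if (spec$structure == "alt") C else 1L
  blk <- if (spec$structure == "alt") cond else rep(1L, length(y))

  ## random-effect groups: (condition, replicate), nested
  re <- fam == "weibull_re"
  if (re) {
    grp_key <- paste(cond, series$replicate, sep = ".")
    grp_lev <- unique(grp_key)
    if (length(grp_lev) < 2L)
      stop("weibull_re requires at least 2 (condition, replicate) groups")
    grp <- match(grp_key, grp_lev)
    G <- length(grp_lev)
  } else {
    grp <- integer(0); G <- 0L
  }

  has_p <- fam %in% c("weibull", "weibull_re")
  per_block <- c("d", "la", "lb", if (has_p) "lp", "ls")
  pnames <- c(as.vector(vapply(seq_len(nb), function(k)
    paste0(per_block, if (nb > 1L) paste0("[", cond_lev[k], "]") else ""),
    character(length(per_block)))),
    if (re) c("ltau", paste0("u[", grp_lev, "]")))
  npb <- length(per_block)
  dim <- length(pnames)

  idx <- function(what, k) (k - 1L) * npb + match(what, per_block)
  i_d <- vapply(seq_len(nb), function(k) idx("d", k), integer(1))
  i_la <- vapply(seq_len(nb), function(k) idx("la", k), integer(1))
  i_lb <- vapply(seq_len(nb), function(k) idx("lb", k), integer(1))
  i_lp <- if (has_p) vapply(seq_len(nb), function(k) idx("lp", k), integer(1))
  i_ls <- vapply(seq_len(nb), function(k) idx("ls", k), integer(1))
  i_ltau <- if (re) nb * npb + 1L
  i_u <- if (re) nb * npb + 1L + seq_len(G)

  pos <- t > 0
  logt <- ifelse(pos, log(t), 0)

  list(series = series, spec = spec, prior = prior, y = y, t = t,
       cond_levels = cond_lev, cond = cond, block = blk, n_blocks = nb,
       grp = grp, n_grp = G, family = fam, has_p = has_p, re = re,
       pnames = pnames, dim = dim, i_d = i_d, i_la = i_la, i_lb = i_lb,
       i_lp = i_lp, i_ls = i_ls, i_ltau = i_ltau, i_u = i_u,
       pos = pos, logt = logt)
}

## Evaluate mean, per-observation partials and pointwise log-lik for an
## unconstrained parameter vector. Returns what both lp and grad need.
.mf_eval <- function(mf, theta) {
  nb <- mf$n_blocks; blk <- mf$block
  d <- theta[mf$i_d][blk]
  a <- exp(theta[mf$i_la])[blk]
  b <- exp(theta[mf$i_lb])[blk]
  sg <- exp(theta[mf$i_ls])[blk]
  pos <- mf$pos
  if (mf$re) {
    tau <- exp(theta[mf$i_ltau])
    uraw <- theta[mf$i_u]
    A <- a + tau * uraw[mf$grp]
  } else {
    tau <- NULL; uraw <- NULL; A <- a
  }
  if (mf$family == "logistic") {
    s <- ifelse(pos, stats::plogis(b * mf$logt), 0)
    g <- s
    dmu_db <- A * s * (1 - s) * mf$logt        # d mu / d b (constrained)
    dmu_dp <- NULL
  } else {
    p <- exp(theta[mf$i_lp])[blk]
    q <- ifelse(pos, (b * mf$t)^p, 0)
    E <- exp(-q)
    g <- ifelse(pos, -expm1(-q), 0)
    dmu_db <- ifelse(pos, A * E * q * p / b, 0)
    dmu_dp <- ifelse(pos, A * E * q * (mf$logt + log(b)), 0)
  }
  mu <- d + A * g
  r <- mf$y - mu
  ll_i <- -log(sg) - 0.918938533204672742 - r^2 / (2 * sg^2)
  list(d = d, a = a, b = b, sg = sg, tau = tau, uraw = uraw, A = A,
       g = g, mu = mu, r = r, ll_i = ll_i,
       dmu_db = dmu_db, dmu_dp = dmu_dp)
}

## log prior (+ log Jacobian of the constraining transform) and its gradient
## on the unconstrained scale.
.mf_prior <- function(mf, theta, grad = FALSE) {
  h <- mf$prior; nb <- mf$n_blocks
  d <- theta[mf$i_d]; la <- theta[mf$i_la]; lb <- theta[mf$i_lb]
  ls <- theta[mf$i_ls]
  sg <- exp(ls)
  lp <- sum(stats::dnorm(d, h$d_loc, h$d_scale, log = TRUE)) +
    sum(stats::dnorm(la, h$a_loc, h$a_scale, log = TRUE)) +
    sum(stats::dnorm(lb, h$b_loc, h$b_scale, log = TRUE)) +
    sum(stats::dexp(sg, rate = h$sigma_rate, log = TRUE) + ls)
  if (mf$has_p) {
    lpv <- theta[mf$i_lp]
    lp <- lp + sum(stats::dnorm(lpv, h$p_loc, h$p_scale, log = TRUE))
  }
  if (mf$re) {
    ltau <- theta[mf$i_ltau]; tau <- exp(ltau); u <- theta[mf$i_u]
    lp <- lp + (-tau^2 / (2 * h$tau_scale^2) + ltau +
                  log(2) - log(h$tau_scale) - 0.918938533204672742) +
      sum(stats::dnorm(u, log = TRUE))
  }
  if (!grad) return(lp)
  gr <- numeric(mf$dim)
  gr[mf$i_d] <- -(d - h$d_loc) / h$d_scale^2
  gr[mf$i_la] <- -(la - h$a_loc) / h$a_scale^2
  gr[mf$i_lb] <- -(lb - h$b_loc) / h$b_scale^2
  gr[mf$i_ls] <- 1 - h$sigma_rate * sg
  if (mf$has_p)
    gr[mf$i_lp] <- -(theta[mf$i_lp] - h$p_loc) / h$p_scale^2
  if (mf$re) {
    tau <- exp(theta[mf$i_ltau])
    gr[mf$i_ltau] <- 1 - tau^2 / h$tau_scale^2
    gr[mf$i_u] <- -theta[mf$i_u]
  }
  list(lp = lp, gr = gr)
}

## Closures used by the sampler and the bridge estimator. `prior_only`
## drops the likelihood term (prior-recovery checks).
.make_logpost <- function(mf, prior_only = FALSE) {
  lik_w <- if (prior_only) 0 else 1
  lp <- function(theta) {
    pr <- .mf_prior(mf, theta, grad = FALSE)
    if (!is.finite(pr)) return(-Inf)
    if (lik_w == 0) return(pr)
    ev <- .mf_eval(mf, theta)
    s <- sum(ev$ll_i)
    if (!is.finite(s)) return(-Inf)
    pr + s
  }
  gr <- function(theta) {
    pr <- .mf_prior(mf, theta, grad = TRUE)
    g <- pr$gr
    if (lik_w == 0) return(g)
    ev <- .mf_eval(mf, theta)
    w <- ev$r / ev$sg^2                      # d ll_i / d mu_i  (negated below)
    nb <- mf$n_blocks; blk <- mf$block
    ## rowsum drops absent blocks; guard by scattering into a dense vector
    sums_by_blk <- function(v) {
      out <- numeric(nb)
      s <- rowsum(v, blk)
      out[as.integer(rownames(s))] <- s
      out
    }
    g[mf$i_d] <- g[mf$i_d] + sums_by_blk(w)
    g[mf$i_la] <- g[mf$i_la] + sums_by_blk(w * ev$g) *
      exp(theta[mf$i_la])                    # chain: d a / d la = a
    g[mf$i_lb] <- g[mf$i_lb] + sums_by_blk(w * ev$dmu_db) *
      exp(theta[mf$i_lb])
    if (mf$has_p)
      g[mf$i_lp] <- g[mf$i_lp] + sums_by_blk(w * ev$dmu_dp) *
        exp(theta[mf$i_lp])
    g[mf$i_ls] <- g[mf$i_ls] + sums_by_blk(-1 + ev$r^2 / ev$sg^2)
    if (mf$re) {
      tau <- ev$tau
      gu <- rowsum(w * ev$g, mf$grp) * tau
      idx <- as.integer(rownames(gu))
      g[mf$i_u][idx] <- g[mf$i_u][idx] + as.numeric(gu)
      g[mf$i_ltau] <- g[mf$i_ltau] +
        sum(w * ev$g * ev$uraw[mf$grp]) * tau
    }
    g
  }
  ll_pointwise <- function(theta) .mf_eval(mf, theta)$ll_i
  list(lp = lp, grad = gr, ll_pointwise = ll_pointwise,
       dim = mf$dim, pnames = mf$pnames)
}

## ---- user-facing likelihood / prior ---------------------------------------

.params_to_theta <- function(mf, params) {
  nb <- mf$n_blocks
  pick <- function(name, n) {
    v <- params[[name]]
    if (is.null(v)) stop("params is missing '", name, "'")
    if (length(v) == 1L) v <- rep(v, n)
    if (length(v) != n)
      stop("params$", name, " must have length 1 or ", n)
    v
  }
  theta <- numeric(mf$dim)
  theta[mf$i_d] <- pick("d", nb)
  theta[mf$i_la] <- log(pick("a", nb))
  theta[mf$i_lb] <- log(pick("b", nb))
  if (mf$has_p) theta[mf$i_lp] <- log(pick("p", nb))
  theta[mf$i_ls] <- log(pick("sigma", nb))
  if (mf$re) {
    tau <- params$tau
    if (is.null(tau)) stop("params is missing 'tau'")
    theta[mf$i_ltau] <- log(tau)
    u <- params$u
    if (is.null(u)) u <- numeric(mf$n_grp)
    if (length(u) != mf$n_grp)
      stop("params$u must have length ", mf$n_grp)
    theta[mf$i_u] <- u / tau                 # stored non-centered
  }
  theta
}

.theta_to_params <- function(mf, theta) {
  out <- list(d = theta[mf$i_d], a = exp(theta[mf$i_la]),
              b = exp(theta[mf$i_lb]),
              sigma = exp(theta[mf$i_ls]))
  if (mf$has_p) out$p <- exp(theta[mf$i_lp])
  if (mf$re) {
    out$tau <- exp(theta[mf$i_ltau])
    out$u <- out$tau * theta[mf$i_u]
  }
  out
}

#' Model log-likelihood of an uptake series
#'
#' Sum of Gaussian log-densities of the observed uptake values around the
#' kinetic mean curve. Under the `"null"` structure a single parameter set
#' is used for every condition; under `"alt"`, `params` entries may be
#' vectors with one entry per condition (sorted condition labels).
#'
#' @param series normalized uptake series (`uptake_da`, `time_s`,
#'   `condition`, `replicate` columns).
#' @param params named list with entries `d`, `a`, `b`, `sigma` (and `p`
#'   for Weibull families; `tau`, `u` for the random-effects family),
#'   scalars or per-condition vectors.
#' @param spec a [model_spec()].
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(series, params, spec) {
  mf <- .model_frame(series, spec)
  theta <- .params_to_theta(mf, params)
  sum(.mf_eval(mf, theta)$ll_i)
}

#' Log prior density of a parameter set
#'
#' Joint log density of the hierarchical prior, on the *constrained*
#' scale (no Jacobian terms). Parameters outside the support give `-Inf`.
#'
#' @inheritParams log_likelihood
#' @param prior an [prior_hyper()] object.
#' @param family model family (determines whether `p`, `tau` are used).
#' @return scalar log prior density.
#' @export
log_prior <- function(params, prior, family = "weibull") {
  stopifnot(inherits(prior, "hdx_prior"), family %in% .FAMILIES)
  h <- prior
  bad <- function(v) any(!is.finite(v) | v <= 0)
  if (bad(params$a) || bad(params$b) || bad(params$sigma)) return(-Inf)
  lp <- sum(stats::dnorm(params$d, h$d_loc, h$d_scale, log = TRUE)) +
    sum(stats::dlnorm(params$a, h$a_loc, h$a_scale, log = TRUE)) +
    sum(stats::dlnorm(params$b, h$b_loc, h$b_scale, log = TRUE)) +
    sum(stats::dexp(params$sigma, rate = h$sigma_rate, log = TRUE))
  if (family %in% c("weibull", "weibull_re")) {
    if (bad(params$p)) return(-Inf)
    lp <- lp + sum(stats::dlnorm(params$p, h$p_loc, h$p_scale, log = TRUE))
  }
  if (family == "weibull_re") {
    if (bad(params$tau)) return(-Inf)
    lp <- lp + stats::dnorm(params$tau, 0, h$tau_scale, log = TRUE) + log(2)
    if (!is.null(params$u))
      lp <- lp + sum(stats::dnorm(params$u, 0, params$tau, log = TRUE))
  }
  lp
}

#' Draw one parameter block from the prior
#'
#' Draws are consistent with [log_prior()]: each marginal follows the
#' stated prior family, respecting positivity constraints.
#'
#' @inheritParams log_prior
#' @param n number of draws.
#' @param n_groups for `"weibull_re"`, how many (condition, replicate)
#'   groups to draw plateau offsets `u` for.
#' @return a data frame with one row per draw.
#' @export
sample_prior <- function(prior, family = "weibull", n = 1, n_groups = 0) {
  stopifnot(inherits(prior, "hdx_prior"), family %in% .FAMILIES)
  h <- prior
  out <- data.frame(
    d = stats::rnorm(n, h$d_loc, h$d_scale),
    a = stats::rlnorm(n, h$a_loc, h$a_scale),
    b = stats::rlnorm(n, h$b_loc, h$b_scale),
    sigma = stats::rexp(n, rate = h$sigma_rate))
  if (family %in% c("weibull", "weibull_re"))
    out$p <- stats::rlnorm(n, h$p_loc, h$p_scale)
  if (family == "weibull_re") {
    out$tau <- abs(stats::rnorm(n, 0, h$tau_scale))
    if (n_groups > 0) {
      u <- matrix(stats::rnorm(n * n_groups), n) * out$tau
      colnames(u) <- paste0("u", seq_len(n_groups))
      out <- cbind(out, u)
    }
  }
  out
}
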