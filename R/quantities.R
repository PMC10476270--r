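#' Posterior draws of the deuterium difference between two states
#'
#' For an alternative-structure fit, evaluates per posterior draw the
#' difference of the condition-specific *mean* uptake curves
#' `delta(t) = mu_A(t) - mu_B(t)` at the requested times. This measures
#' the condition effect on the kinetics; to obtain the spread of
#' predicted *observations* instead, set `predictive = TRUE`, which adds
#' independent Gaussian noise from both conditions to every draw.
#'
#' @param fit an alternative-structure [fit_peptide()] result with both
#'   states present.
#' @param pair character vector `c(A, B)` of condition labels; the
#'   difference is state A minus state B.
#' @param times times (seconds) at which to evaluate the difference.
#' @param predictive add observation noise (default `FALSE`).
#' @return an object of class `hdx_delta`: matrix of draws (rows) by
#'   times (columns) with attributes `times` and `pair`.
#' @export
delta_draws <- function(fit, pair, times, predictive = FALSE) {
  stopifnot(inherits(fit, "hdx_fit"), length(pair) == 2)
  mf <- fit$mf
  if (mf$spec$structure != "alt")
    stop("delta_draws requires an alternative-structure (context-specific) fit")
  ia <- match(as.character(pair[1]), mf$cond_levels)
  ib <- match(as.character(pair[2]), mf$cond_levels)
  if (is.na(ia) || is.na(ib))
    stop("unknown condition label: ",
         paste(pair[is.na(c(ia, ib))], collapse = ", "))
  fam <- if (mf$family == "logistic") "logistic" else "weibull"
  S <- nrow(fit$draws_u)
  out <- matrix(NA_real_, S, length(times))
  for (s in seq_len(S)) {
    pars <- .theta_to_params(mf, fit$draws_u[s, ])
    mu_a <- .mean_curve(fam, times, pars$a[ia], pars$b[ia],
                        if (!is.null(pars$p)) pars$p[ia], pars$d[ia])
    mu_b <- .mean_curve(fam, times, pars$a[ib], pars$b[ib],
                        if (!is.null(pars$p)) pars$p[ib], pars$d[ib])
    out[s, ] <- mu_a - mu_b
    if (predictive)
      out[s, ] <- out[s, ] +
        stats::rnorm(length(times), 0,
                     sqrt(pars$sigma[ia]^2 + pars$sigma[ib]^2))
  }
  colnames(out) <- as.character(times)
  structure(out, times = times, pair = as.character(pair),
            class = c("hdx_delta", "matrix", "array"))
}

.delta_col <- function(dd, t) {
  j <- match(t, attr(dd, "times"))
  if (is.na(j)) stop("time ", t, " was not among the computed times")
  dd[, j]
}

#' Posterior probability that the deuterium difference exceeds a value
#'
#' `P(delta(t) > d)`, the fraction of posterior draws above the
#' threshold. Nonincreasing in `d`.
#'
#' @param dd an [delta_draws()] object.
#' @param d threshold (uptake units).
#' @param t time (seconds); default: all computed times.
#' @return named vector of probabilities in `[0, 1]`.
#' @export
prob_exceed <- function(dd, d, t = NULL) {
  stopifnot(inherits(dd, "hdx_delta"))
  if (is.null(t)) t <- attr(dd, "times")
  p <- vapply(t, function(tt) mean(.delta_col(dd, tt) > d), numeric(1))
  stats::setNames(p, as.character(t))
}

#' Largest difference threshold attaining a given exceedance probability
#'
#' Inverts [prob_exceed()]: the largest `d` with
#' `P(delta(t) > d) = p` is the `(1 - p)` empirical quantile of the
#' posterior difference draws (type-7 interpolation). A negative result
#' at high `p` indicates deuterium incorporation in the opposite state
#' of the pair ordering.
#'
#' @param dd an [delta_draws()] object.
#' @param p exceedance probability in (0, 1).
#' @param t time (seconds); default: all computed times.
#' @return named vector of thresholds `d*`.
#' @export
largest_d_at_prob <- function(dd, p, t = NULL) {
  stopifnot(inherits(dd, "hdx_delta"), p > 0, p < 1)
  if (is.null(t)) t <- attr(dd, "times")
  q <- vapply(t, function(tt)
    stats::quantile(.delta_col(dd, tt), probs = 1 - p, type = 7,
                    names = FALSE), numeric(1))
  stats::setNames(q, as.character(t))
}

#' Temporal profile of exceedance probabilities or thresholds
#'
#' @param dd an [delta_draws()] object.
#' @param d threshold(s); a row per `d` and time is produced with the
#'   exceedance probability.
#' @param p probability level(s); a row per `p` and time with the
#'   largest threshold `d*`.
#' @return long data frame: `time_s`, and `threshold_d`, `prob` (for
#'   `d`) or `p`, `largest_d` (for `p`).
#' @export
temporal_profile <- function(dd, d = NULL, p = NULL) {
  stopifnot(inherits(dd, "hdx_delta"))
  if (is.null(d) == is.null(p))
    stop("give exactly one of 'd' or 'p'")
  times <- attr(dd, "times")
  if (!is.null(d)) {
    out <- expand.grid(time_s = times, threshold_d = d)
    out$prob <- mapply(function(tt, dv) unname(prob_exceed(dd, dv, tt)),
                       out$time_s, out$threshold_d)
  } else {
    out <- expand.grid(time_s = times, p = p)
    out$largest_d <- mapply(function(tt, pv)
      unname(largest_d_at_prob(dd, pv, tt)), out$time_s, out$p)
  }
  out
}

#' Protein-ordered matrix of per-peptide quantities
#'
#' Arranges per-peptide values (e.g. exceedance probabilities per time)
#' into a matrix ordered by residue span (start, then end) for heat-map
#' style epitope visualization. Peptides without a span are appended in
#' input order and flagged with a warning.
#'
#' @param results data frame with `peptide`, optionally `start`, `end`,
#'   and one or more value columns.
#' @param values names of the value columns (default: all numeric
#'   columns except `start`/`end`).
#' @return numeric matrix with peptides as ordered rows and an attribute
#'   `spans` giving the ordering used.
#' @export
protein_map <- function(results, values = NULL) {
  stopifnot("peptide" %in% names(results))
  if (is.null(values))
    values <- setdiff(names(results)[vapply(results, is.numeric,
                                            logical(1))],
                      c("start", "end"))
  if (!length(values)) stop("no value columns to map")
  has_span <- if (all(c("start", "end") %in% names(results)))
    !(is.na(results$start) | is.na(results$end))
  else rep(FALSE, nrow(results))
  if (any(!has_span))
    warning(sum(!has_span), " peptide(s) without residue span appended ",
            "in input order", call. = FALSE)
  o_span <- which(has_span)[order(results$start[has_span],
                                  results$end[has_span])]
  o <- c(o_span, which(!has_span))
  m <- as.matrix(results[o, values, drop = FALSE])
  rownames(m) <- as.character(results$peptide[o])
  attr(m, "spans") <- if (all(c("start", "end") %in% names(results)))
    results[o, intersect(c("peptide", "start", "end"), names(results))]
  m
}
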