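#' Differential solvent-accessibility z-scores
#'
#' Per-residue accessible surface areas (ASA) of the unbound and bound
#' structures are square-root transformed (variance-stabilizing, linear
#' scale), differenced (unbound minus bound), and standardized to
#' z-scores across residues. Positive z indicates higher accessibility
#' in the unbound form (burial upon binding).
#'
#' @param table data frame with columns `residue`, `asa_unbound`,
#'   `asa_bound` (nonnegative, aligned residue indices).
#' @return data frame `residue`, `z`; the `degenerate` attribute is
#'   `TRUE` when the differences have zero variance (all z set to 0).
#' @export
dasa_zscores <- function(table) {
  need <- c("residue", "asa_unbound", "asa_bound")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(table$residue))
    stop("misaligned tables: duplicated residue index")
  if (any(table$asa_unbound < 0 | table$asa_bound < 0))
    stop("ASA values must be nonnegative")
  d <- sqrt(table$asa_unbound) - sqrt(table$asa_bound)
  s <- stats::sd(d)
  degenerate <- !is.finite(s) || s == 0
  z <- if (degenerate) rep(0, length(d)) else (d - mean(d)) / s
  if (degenerate)
    warning("zero variance in ASA differences; all z-scores set to 0",
            call. = FALSE)
  structure(data.frame(residue = table$residue, z = z),
            degenerate = degenerate)
}

#' Local false discovery rate of z-scores
#'
#' Two-group empirical-null model: the marginal density `f` is estimated
#' by a Gaussian kernel density, the null component `f0` is a normal
#' density with location/scale estimated robustly from the central mass
#' of the z-scores (median and median absolute deviation), and the null
#' proportion by the density ratio at the null center. The local fdr is
#' `fdr(z) = pi0 f0(z) / f(z)`, clipped to `[0, 1]`; residues with
#' `fdr < threshold` are called significant.
#'
#' @param z numeric z-scores (at least 20 for density estimation).
#' @param threshold call threshold on the local fdr (default 0.01).
#' @return data frame `z`, `lfdr`, `call` with attributes `pi0`, `mu0`,
#'   `sigma0`.
#' @export
local_fdr <- function(z, threshold = 0.01) {
  stopifnot(is.numeric(z), threshold > 0, threshold < 1)
  if (length(z) < 20)
    stop("need at least 20 z-scores for density estimation; ",
         "use plain z-score thresholding for smaller tables")
  mu0 <- stats::median(z)
  sigma0 <- stats::mad(z)
  if (sigma0 <= 0) sigma0 <- stats::sd(z)
  if (!is.finite(sigma0) || sigma0 <= 0)
    stop("degenerate z-scores: no spread to estimate the null from")
  dens <- stats::density(z, n = 1024, cut = 4)
  f <- stats::approx(dens$x, dens$y, xout = z, rule = 2)$y
  f <- pmax(f, 1e-12)
  f0 <- stats::dnorm(z, mu0, sigma0)
  pi0 <- min(1, max(stats::approx(dens$x, dens$y, xout = mu0, rule = 2)$y /
                      stats::dnorm(mu0, mu0, sigma0), 1e-3))
  lfdr <- pmin(1, pmax(0, pi0 * f0 / f))
  structure(data.frame(z = z, lfdr = lfdr, call = lfdr < threshold),
            pi0 = pi0, mu0 = mu0, sigma0 = sigma0)
}

#' End-to-end differential solvent accessibility analysis
#'
#' @param table as in [dasa_zscores()], or a CSV path with those columns.
#' @param threshold local fdr call threshold.
#' @return data frame `residue`, `z`, `lfdr`, `call`.
#' @export
dasa_analysis <- function(table, threshold = 0.01) {
  if (is.character(table)) table <- utils::read.csv(table)
  zs <- dasa_zscores(table)
  if (isTRUE(attr(zs, "degenerate"))) {
    out <- data.frame(residue = zs$residue, z = zs$z, lfdr = 1,
                      call = FALSE)
    return(out)
  }
  lf <- local_fdr(zs$z, threshold)
  data.frame(residue = zs$residue, z = zs$z, lfdr = lf$lfdr,
             call = lf$call)
}
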