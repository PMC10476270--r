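#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) computation: the probability that a random
#' positive is scored above a random negative, with ties contributing
#' one half. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores or probabilities, higher = more positive.
#' @param labels binary labels (0/1 or logical) of the same length.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)), all(is.finite(scores)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0)
    stop("AUROC needs at least one positive and one negative label")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between forecast probabilities and binary
#' outcomes; 0 is perfect calibration, 0.25 is an uninformative constant
#' forecast of one half.
#'
#' @param probs forecast probabilities in `[0, 1]`.
#' @param labels binary outcomes.
#' @return Brier score in `[0, 1]`.
#' @export
brier <- function(probs, labels) {
  labels <- as.integer(labels)
  stopifnot(length(probs) == length(labels), all(labels %in% c(0L, 1L)))
  if (any(!is.finite(probs) | probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  mean((probs - labels)^2)
}

#' Benchmark differential-test results against simulator truth
#'
#' @param results data frame with `peptide` and `prob_alt` (e.g. from
#'   [test_all_peptides()]).
#' @param labels per-peptide truth, e.g. `simulate_dataset()$labels`
#'   (uses the `label` column).
#' @return one-row data frame with `n`, `auroc`, `brier`.
#' @export
benchmark_results <- function(results, labels) {
  m <- merge(results, labels, by = "peptide")
  if (nrow(m) == 0) stop("no overlapping peptides between results and truth")
  auc <- tryCatch(auroc(m$prob_alt, m$label), error = function(e) NA_real_)
  data.frame(n = nrow(m), auroc = auc, brier = brier(m$prob_alt, m$label))
}
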