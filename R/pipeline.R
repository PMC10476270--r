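#' Run the full differential HDX-MS workflow
#'
#' Reads (or simulates) an uptake table, normalizes it, tests every
#' peptide for a condition effect, optionally computes posterior
#' deuterium-difference quantities, and writes all results together with
#' the resolved configuration (including the seed) to an output
#' directory. Peptides that fail are listed in `failed.csv` with their
#' error message, never dropped silently.
#'
#' @param config a named list, or the path of a YAML file, with entries:
#' \describe{
#'   \item{input}{path of an uptake CSV (alternative to `simulate`).}
#'   \item{simulate}{list passed to [sim_config()] to generate data.}
#'   \item{family}{kinetic family (default `"weibull"`).}
#'   \item{prior_odds}{prior odds null/alternative (default 3).}
#'   \item{mcmc}{list of [mcmc_config()] overrides.}
#'   \item{bridge}{list of [bridge_config()] overrides.}
#'   \item{quantities}{list with `pair` (two condition labels), and
#'     `d` and/or `p` values for the difference computations.}
#'   \item{seed}{integer seed (default 1).}
#'   \item{out_dir}{output directory (default `"hdxbayes_results"`).}
#' }
#' @param verbose print per-peptide progress.
#' @return (invisibly) list with `results`, `quantities`, `failed`,
#'   `truth` (when simulated), `out_dir`.
#' @export
run_differential <- function(config, verbose = interactive()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  family <- config$family %||% "weibull"
  prior_odds <- config$prior_odds %||% 3
  seed <- as.integer(config$seed %||% 1)
  out_dir <- config$out_dir %||% "hdxbayes_results"
  mcmc <- do.call(mcmc_config, utils::modifyList(list(seed = seed),
                                                 config$mcmc %||% list()))
  bridge <- do.call(bridge_config, config$bridge %||% list())

  truth <- NULL
  if (!is.null(config$input)) {
    data <- read_uptake_csv(config$input)
  } else if (!is.null(config$simulate)) {
    sim_args <- utils::modifyList(list(seed = seed), config$simulate)
    sim <- simulate_dataset(do.call(sim_config, sim_args))
    data <- sim$data
    truth <- sim$labels
  } else stop("config needs either 'input' or 'simulate'")
  data <- normalize_uptake(data)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- unique(as.character(data$peptide))
  res <- vector("list", length(ids))
  qua <- list(prob = NULL, largest_d = NULL)
  failed <- character(0)
  qcfg <- config$quantities
  for (i in seq_along(ids)) {
    ser <- data[data$peptide == ids[i], , drop = FALSE]
    step <- tryCatch({
      cfg_i <- mcmc; cfg_i$seed <- seed + 2L * (i - 1L)
      r <- test_peptide(ser, family = family, cfg = cfg_i,
                        bridge = bridge, prior_odds = prior_odds,
                        keep_fits = !is.null(qcfg))
      if (!is.null(qcfg)) {
        fit_alt <- attr(r, "fit_alt")
        pair <- qcfg$pair %||% sort(unique(as.character(ser$condition)))[1:2]
        times <- qcfg$times %||% sort(unique(ser$time_s[ser$time_s > 0]))
        dd <- delta_draws(fit_alt, pair, times)
        span <- c(start = ser$start[1] %||% NA, end = ser$end[1] %||% NA)
        if (!is.null(qcfg$d)) {
          tp <- temporal_profile(dd, d = qcfg$d)
          qua$prob <- rbind(qua$prob,
                            cbind(peptide = ids[i], start = span[1],
                                  end = span[2], tp, row.names = NULL))
        }
        if (!is.null(qcfg$p)) {
          tp <- temporal_profile(dd, p = qcfg$p)
          qua$largest_d <- rbind(qua$largest_d,
                                 cbind(peptide = ids[i], tp,
                                       row.names = NULL))
        }
      }
      r
    }, error = function(e) conditionMessage(e))
    if (is.character(step)) {
      failed[ids[i]] <- step
      if (verbose) message(ids[i], ": FAILED (", step, ")")
    } else {
      res[[i]] <- step
      if (verbose)
        message(sprintf("%s: prob_alt = %.3f%s", ids[i], step$prob_alt,
                        if (nzchar(step$flags))
                          paste0(" [", step$flags, "]") else ""))
    }
  }
  results <- do.call(rbind, res[!vapply(res, is.null, logical(1))])

  utils::write.csv(results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  if (!is.null(qua$prob))
    utils::write.csv(qua$prob, file.path(out_dir, "quantities_prob.csv"),
                     row.names = FALSE)
  if (!is.null(qua$largest_d))
    utils::write.csv(qua$largest_d,
                     file.path(out_dir, "quantities_largest_d.csv"),
                     row.names = FALSE)
  if (length(failed))
    utils::write.csv(data.frame(peptide = names(failed), error = failed),
                     file.path(out_dir, "failed.csv"), row.names = FALSE)
  if (!is.null(truth))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  resolved <- utils::modifyList(
    config, list(family = family, prior_odds = prior_odds, seed = seed,
                 out_dir = out_dir,
                 mcmc = unclass(mcmc), bridge = unclass(bridge)))
  yaml::write_yaml(resolved, file.path(out_dir, "config.yaml"))
  invisible(list(results = results, quantities = qua, failed = failed,
                 truth = truth, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
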