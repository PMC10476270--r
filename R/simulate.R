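#' Simulation-study generator
#'
#' @description
#' Forward-simulates a full differential HDX-MS experiment at the isotope
#' envelope level, with known ground truth:
#'
#' 1. peptide sequences of uniform random length 5--25, residues drawn
#'    uniformly from the 20 canonical amino acids;
#' 2. a nondecreasing *incorporation schedule* per peptide: a Dirichlet
#'    draw with concentration `20/(i-1)` for component `i-1`, whose
#'    cumulative sums give the deuteration fraction at each time point
#'    after zero;
#' 3. per-time condition-effect indicators `z ~ Bernoulli(0.05)`; at each
#'    flagged time the remaining schedule of the perturbed condition is
#'    resampled;
#' 4. isotope envelopes: a binomial natural-abundance model for the
#'    undeuterated envelope, convolved with binomial deuterium
#'    incorporation over the exchangeable amides (prolines and the two
#'    N-terminal residues excluded), sampled at finite ion statistics;
#' 5. centroiding of the simulated spectra into the canonical uptake
#'    table consumed by the rest of the package.
#'
#' @name hdx-simulate
NULL

## monoisotopic residue masses (Da)
.AA_MONO <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
              V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
              I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
              K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
              F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
.MASS_H2O <- 18.010565
.MASS_PROTON <- 1.007276
.MASS_C13 <- 1.003355      # 13C - 12C
.MASS_DH <- 1.00628        # D - H
.AVERAGINE_C <- 4.9384     # carbons per residue
.P_C13 <- 0.0107           # natural 13C abundance

#' Simulation configuration
#'
#' Scenario presets follow the simulation study design: 100 peptides,
#' per-time effect probability 0.05, Dirichlet base 20, and
#' \itemize{
#'   \item scenario A: 4 time points, 3 replicates, 2 conditions;
#'   \item scenario B: 4 time points, 2 replicates, 2 conditions;
#'   \item scenario C: 5 time points, 2 replicates, 2 conditions.
#' }
#' Exposure times are in seconds, log-spaced as in typical continuous
#' labeling experiments, and always start at `t = 0`.
#'
#' @param scenario `"A"`, `"B"`, `"C"` or `"custom"`.
#' @param n_peptides number of peptides.
#' @param times strictly increasing exposure times with `times[1] == 0`
#'   (required for `"custom"`, preset otherwise).
#' @param replicates,conditions design size (preset by scenario).
#' @param effect_p per-time-point probability that the perturbed
#'   condition's incorporation is resampled (`P(z = 1) = effect_p`).
#' @param dirichlet_base base concentration of the schedule Dirichlet.
#' @param n_ions ions sampled per simulated spectrum (counting noise).
#' @param seed integer seed for the generator.
#' @return an object of class `hdx_sim_config`.
#' @export
sim_config <- function(scenario = c("A", "B", "C", "custom"),
                       n_peptides = 100, times = NULL, replicates = NULL,
                       conditions = 2, effect_p = 0.05,
                       dirichlet_base = 20, n_ions = 10000, seed = 1) {
  scenario <- match.arg(scenario)
  preset <- switch(scenario,
                   A = list(times = c(0, 30, 300, 3600), replicates = 3),
                   B = list(times = c(0, 30, 300, 3600), replicates = 2),
                   C = list(times = c(0, 30, 120, 600, 3600),
                            replicates = 2),
                   custom = list(times = times, replicates = replicates))
  times <- if (is.null(times) || scenario != "custom") preset$times else times
  replicates <- if (is.null(replicates)) preset$replicates else replicates
  if (is.null(times) || is.null(replicates))
    stop("custom scenario requires 'times' and 'replicates'")
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing and start at 0")
  if (length(times) < 2) stop("need at least 2 time points")
  stopifnot(n_peptides >= 1, replicates >= 1, conditions >= 1,
            effect_p >= 0, effect_p <= 1, dirichlet_base > 0, n_ions >= 1)
  structure(list(scenario = scenario, n_peptides = as.integer(n_peptides),
                 times = times, replicates = as.integer(replicates),
                 conditions = as.integer(conditions), effect_p = effect_p,
                 dirichlet_base = dirichlet_base, n_ions = as.integer(n_ions),
                 seed = as.integer(seed)),
            class = "hdx_sim_config")
}

#' Sample a random peptide sequence
#'
#' Length uniform on 5..25; residues i.i.d. uniform over the 20 canonical
#' amino acids.
#'
#' @return a single-character amino-acid string.
#' @export
sample_peptide <- function() {
  len <- sample(5:25, 1)
  paste(sample(names(.AA_MONO), len, replace = TRUE), collapse = "")
}

#' Count exchangeable backbone amides of a peptide
#'
#' Prolines (no amide hydrogen) and the first two residues (fast
#' back-exchange) do not contribute.
#'
#' @param sequence amino-acid string.
#' @return integer count, `max(0, length - 2 - prolines at position 3+)`.
#' @export
exchangeable_sites <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) < 1) stop("empty sequence")
  if (!all(aa %in% names(.AA_MONO)))
    stop("non-canonical residue(s): ",
         paste(unique(aa[!aa %in% names(.AA_MONO)]), collapse = ", "))
  if (length(aa) <= 2) return(0L)
  tail_aa <- aa[-(1:2)]
  max(0L, length(tail_aa) - sum(tail_aa == "P"))
}

#' Draw a nondecreasing incorporation schedule
#'
#' A Dirichlet vector `pi` of dimension `m - 1` is drawn with
#' concentration `alpha[i] = base / i` for components `i = 1..m-1`
#' (the component feeding the incorporation step into time point
#' `i + 1`). The schedule is its cumulative sum: the deuteration
#' fraction at time point `i > 1` is `D_i = sum(pi[1:(i-1)])`, which is
#' nondecreasing with `D_1 = 0` at time zero and `D_m = 1`.
#'
#' @param m number of time points (including `t = 0`), `m >= 2`.
#' @param base Dirichlet base concentration (default 20).
#' @return numeric vector of length `m`: `c(0, D_2, ..., D_m)`.
#' @export
incorporation_schedule <- function(m, base = 20) {
  if (m < 2) stop("need m >= 2 time points")
  alpha <- base / seq_len(m - 1)
  g <- stats::rgamma(m - 1, shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha      # guard against all-zero gamma draws
  pi_vec <- g / sum(g)
  out <- c(0, cumsum(pi_vec))
  out[m] <- 1                      # pin the simplex total exactly
  out
}

#' Apply a condition effect to an incorporation schedule
#'
#' For each time point after zero an indicator `z ~ Bernoulli(effect_p)`
#' is drawn. At each flagged time point the remaining schedule is
#' replaced by the corresponding tail of a freshly drawn schedule (the
#' effect persists), and monotonicity is restored by a running maximum.
#' Because every complete schedule ends at full incorporation, a flag at
#' the final time point cannot change the schedule; the returned
#' `realized` indicators mark the flags that actually perturbed the
#' schedule, and are the ones a differential method can possibly detect.
#'
#' @param schedule length-`m` schedule from [incorporation_schedule()].
#' @param effect_p per-time-point effect probability.
#' @param base Dirichlet base concentration used for resampling.
#' @return list with `schedule` (perturbed), `z` (drawn indicators,
#'   length `m - 1`, for time points `2..m`) and `realized` (indicators
#'   of realized schedule changes).
#' @export
apply_condition_effect <- function(schedule, effect_p = 0.05, base = 20) {
  m <- length(schedule)
  stopifnot(m >= 2, !is.unsorted(schedule), schedule[1] == 0)
  z <- stats::rbinom(m - 1, 1, effect_p)
  realized <- integer(m - 1)
  out <- schedule
  for (i in which(z == 1L) + 1L) {         # absolute time index in 2..m
    fresh <- incorporation_schedule(m, base)
    old_tail <- out[i:m]
    out[i:m] <- fresh[i:m]
    out <- cummax(out)
    realized[i - 1L] <- as.integer(any(abs(out[i:m] - old_tail) > 1e-12))
  }
  list(schedule = out, z = z, realized = realized)
}

## undeuterated isotope envelope: binomial heavy-isotope model over the
## averagine carbon count
.iso_envelope <- function(n_residues, kmax = NULL) {
  nC <- max(1L, round(.AVERAGINE_C * n_residues))
  if (is.null(kmax)) kmax <- min(nC, stats::qbinom(1 - 1e-8, nC, .P_C13) + 2L)
  k <- 0:kmax
  w <- stats::dbinom(k, nC, .P_C13)
  list(k = k, w = w / sum(w))
}

#' Simulate an isotope spectrum of a (partially) deuterated peptide
#'
#' The undeuterated envelope follows a binomial natural-abundance model
#' over the peptide's averagine-estimated carbon count; deuteration adds
#' a `Binomial(n_exchangeable, D)` number of mass shifts per ion. A
#' finite number of ions is sampled, giving realistic counting noise in
#' the centroid.
#'
#' @param sequence amino-acid string.
#' @param incorporation deuteration fraction `D` in `[0, 1]`.
#' @param charge precursor charge state.
#' @param n_ions ions sampled for the spectrum.
#' @return an [isotope_distribution()] with peaks at
#'   `(M + k 13C + j D-H + z proton) / z`.
#' @export
simulate_spectrum <- function(sequence, incorporation, charge = 2,
                              n_ions = 1000) {
  stopifnot(incorporation >= 0, incorporation <= 1, charge >= 1, n_ions >= 1)
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (!all(aa %in% names(.AA_MONO)))
    stop("non-canonical residue(s) in sequence")
  M0 <- sum(.AA_MONO[aa]) + .MASS_H2O
  env <- .iso_envelope(length(aa))
  nex <- exchangeable_sites(sequence)
  j <- 0:nex
  wd <- if (nex == 0) 1 else stats::dbinom(j, nex, incorporation)
  ## joint (13C shift, deuterium count) grid
  pmf <- outer(env$w, wd)
  mass <- outer(env$k * .MASS_C13, j * .MASS_DH, `+`) + M0
  counts <- stats::rmultinom(1, n_ions, as.vector(pmf))[, 1]
  keep <- counts > 0
  mz <- (as.vector(mass)[keep] + charge * .MASS_PROTON) / charge
  o <- order(mz)
  isotope_distribution(mz = mz[o], intensity = counts[keep][o],
                       charge = charge)
}

#' Simulate a complete differential HDX-MS data set
#'
#' Generates the full experiment of a [sim_config()] scenario: per
#' peptide a base incorporation schedule (condition 1) and, for each
#' further condition, a perturbed schedule via
#' [apply_condition_effect()]; then per (condition, replicate, time) a
#' simulated spectrum and its centroid. Roughly `1 - effect_p` of the
#' per-time indicators are null.
#'
#' @param cfg a [sim_config()].
#' @return list with
#' \describe{
#'   \item{data}{uptake table in the canonical schema (`peptide`,
#'     `sequence`, `start`, `end`, `charge`, `condition`, `replicate`,
#'     `time_s`, `centroid_mz`).}
#'   \item{truth}{data frame of per (peptide, condition, time point)
#'     indicators: `z` as drawn, `realized` as materialized in the
#'     schedules.}
#'   \item{labels}{per-peptide data frame: `label_drawn` (any `z = 1`)
#'     and `label` (any realized change; the detectable ground truth).}
#'   \item{schedules}{list of per-condition schedules per peptide.}
#' }
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "hdx_sim_config"))
  set.seed(cfg$seed)
  m <- length(cfg$times)
  rows <- vector("list", cfg$n_peptides)
  truth <- vector("list", cfg$n_peptides)
  labels <- vector("list", cfg$n_peptides)
  schedules <- vector("list", cfg$n_peptides)

  starts <- sample.int(400, cfg$n_peptides, replace = TRUE)
  for (ip in seq_len(cfg$n_peptides)) {
    pep_id <- sprintf("pep%03d", ip)
    seq_i <- sample_peptide()
    charge <- sample(1:3, 1)
    base_sched <- incorporation_schedule(m, cfg$dirichlet_base)
    scheds <- list(base_sched)
    tr <- NULL
    if (cfg$conditions >= 2) {
      for (cc in 2:cfg$conditions) {
        eff <- apply_condition_effect(base_sched, cfg$effect_p,
                                      cfg$dirichlet_base)
        scheds[[cc]] <- eff$schedule
        tr <- rbind(tr, data.frame(
          peptide = pep_id, condition = paste0("C", cc),
          time_s = cfg$times[-1], z = eff$z, realized = eff$realized))
      }
    }
    schedules[[ip]] <- scheds
    truth[[ip]] <- tr
    labels[[ip]] <- data.frame(
      peptide = pep_id,
      label_drawn = as.integer(!is.null(tr) && any(tr$z == 1L)),
      label = as.integer(!is.null(tr) && any(tr$realized == 1L)))

    des <- expand.grid(time_idx = seq_len(m),
                       replicate = seq_len(cfg$replicates),
                       condition = seq_len(cfg$conditions))
    cent <- numeric(nrow(des))
    for (k in seq_len(nrow(des))) {
      D <- scheds[[des$condition[k]]][des$time_idx[k]]
      sp <- simulate_spectrum(seq_i, D, charge = charge,
                              n_ions = cfg$n_ions)
      cent[k] <- sum(sp$mz * sp$intensity) / sum(sp$intensity)
    }
    rows[[ip]] <- data.frame(
      peptide = pep_id, sequence = seq_i,
      start = starts[ip], end = starts[ip] + nchar(seq_i) - 1L,
      charge = charge, condition = paste0("C", des$condition),
      replicate = des$replicate, time_s = cfg$times[des$time_idx],
      centroid_mz = cent, stringsAsFactors = FALSE)
  }
  list(data = do.call(rbind, rows),
       truth = do.call(rbind, truth),
       labels = do.call(rbind, labels),
       schedules = schedules)
}
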