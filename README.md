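# hdxbayes

Bayesian functional analysis of differential hydrogen–deuterium
exchange mass spectrometry (HDX-MS) data.

HDX-MS measures how fast a protein's backbone amides exchange hydrogen
for deuterium in heavy water; a binding partner that shields part of the
surface slows the deuterium uptake of peptides covering it. Deciding
*which* peptides respond to a condition — ligand, antibody, mutation —
is a statistical problem: uptake is a noisy time course, replication is
often minimal, and practitioners need calibrated probabilities rather
than yes/no calls. `hdxbayes` is for mass-spectrometry and structural
biology groups doing epitope mapping or conformational analysis who want
those probabilities.

## The model

Per peptide, uptake `y` at exposure time `t` in condition `c` is
Gaussian around a smooth saturation curve, either logistic

    mu_c(t) = d_c + a_c / (1 + exp(-b_c log t))

or Weibull

    mu_c(t) = d_c + a_c (1 - exp(-(b_c t)^p_c))

with plateau `a`, rate `b`, stretching exponent `p`, intercept `d` and
noise SD `sigma` (a random-effects variant adds replicate-level plateau
offsets). The hypothesis test is Bayesian model selection between a
**null** model whose single parameter block is blind to the condition
and an **alternative** with condition-specific blocks:

    posterior odds = (pi0 / pi1)^-1 * BF10,
    BF10 = p(D | M1) / p(D | M0)

Marginal likelihoods are estimated by iterative optimal **bridge
sampling** from Hamiltonian Monte Carlo posterior draws, and
`P(M1 | D) = BF / (BF + pi0/pi1)` with prior odds defaulting to 3:1 in
favor of the null (multiplicity control). Because the fit is fully
Bayesian, the posterior also yields epitope-mapping quantities such as
`P(Δdeuterium(A,B)(t) > d)` for any effect size `d`, and its inversion —
the largest `d` attaining a given probability. PSIS-LOO
cross-validation, prior/posterior predictive checks, a full
isotope-envelope simulation-study generator with ground truth, AUROC /
Brier calibration metrics, and a differential solvent-accessibility
(local fdr) module round out the workflow. The methods vignette
(`vignettes/hdxbayes-methods.Rmd`) documents every modeling choice.

## Worked example

Simulate a small two-condition experiment with known truth, test every
peptide, and interrogate the one real effect:

```r
library(hdxbayes)

sim    <- simulate_dataset(sim_config("A", n_peptides = 5, seed = 5))
uptake <- normalize_uptake(sim$data)        # centroid m/z -> uptake (Da)

results <- test_all_peptides(
  uptake, family = "weibull",
  cfg = mcmc_config(chains = 2, warmup = 750, samples = 500, seed = 7))

cbind(results[, c("peptide", "log_bf", "prob_alt")],
      label = sim$labels$label)
#>   peptide log_bf prob_alt label
#> 1  pep001  -24.3 9.71e-12     0
#> 2  pep002  -22.0 9.02e-11     0
#> 3  pep003  -21.5 1.55e-10     0
#> 4  pep004   13.6 1.00e+00     1
#> 5  pep005  -22.4 6.19e-11     0
```

`log_bf` is the log Bayes factor for the condition-specific model; the
four unperturbed peptides get posterior probabilities ~1e-10 and the
planted effect is called with probability 1. Where is the effect, and
how big?

```r
tst <- test_peptide(uptake[uptake$peptide == "pep004", ],
                    cfg = mcmc_config(chains = 2, warmup = 750,
                                      samples = 500, seed = 7),
                    keep_fits = TRUE)
dd <- delta_draws(attr(tst, "fit_alt"), c("C2", "C1"),
                  times = c(30, 300, 3600))

prob_exceed(dd, d = 0.2)          # P(uptake difference > 0.2 Da)
#>   30  300 3600
#>    0    1    0
largest_d_at_prob(dd, p = 0.95)   # largest d with P(delta > d) = 0.95
#>     30    300   3600
#> -0.024  0.323 -0.037
```

The perturbation acts at 300 s only: the deuterium difference exceeds
0.32 Da there with 95% posterior probability, and is indistinguishable
from zero at 30 s and 3600 s (full saturation). Against the simulator's
truth labels:

```r
benchmark_results(results, sim$labels)
#>   n auroc        brier
#> 1 5     1 2.918668e-12
```

A thin command-line wrapper (`inst/cli/hdxbayes`) exposes `simulate`,
`test`, `benchmark` and `dasa` subcommands over the same functions, and
`run_differential()` drives the whole pipeline from a YAML config.

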