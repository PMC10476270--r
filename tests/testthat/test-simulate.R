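test_that("sampled peptides have uniform lengths and canonical residues", {
  set.seed(50)
  seqs <- replicate(5000, sample_peptide())
  lens <- nchar(seqs)
  expect_true(all(lens >= 5 & lens <= 25))
  chi <- chisq.test(table(factor(lens, levels = 5:25)))
  expect_gt(chi$p.value, 1e-4)
  expect_true(all(strsplit(paste(seqs, collapse = ""), "")[[1]] %in%
                    strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]]))
  set.seed(99); s1 <- sample_peptide()
  set.seed(99); s2 <- sample_peptide()
  expect_identical(s1, s2)
})

test_that("exchangeable sites exclude prolines and the N-terminal pair", {
  expect_equal(exchangeable_sites("GAGAGA"), 4L)
  expect_equal(exchangeable_sites("GAPAGA"), 3L)
  expect_equal(exchangeable_sites("PPPPP"), 0L)
  expect_equal(exchangeable_sites("PPGGG"), 3L)  # leading P's cost nothing extra
  expect_equal(exchangeable_sites("GA"), 0L)
  expect_error(exchangeable_sites("GAXZA"), "non-canonical")
})

test_that("incorporation schedules are cumulative over the simplex", {
  set.seed(51)
  for (m in c(2, 4, 5, 8)) {
    for (r in 1:50) {
      s <- incorporation_schedule(m)
      expect_length(s, m)
      expect_equal(s[1], 0)
      expect_true(all(diff(s) >= 0))
      expect_true(all(s >= 0 & s <= 1 + 1e-12))
      expect_equal(s[m], 1)
    }
  }
  expect_error(incorporation_schedule(1), "m >= 2")
  ## m = 2 is the degenerate one-component simplex
  expect_equal(incorporation_schedule(2), c(0, 1))
})

test_that("the mean early incorporation matches the Dirichlet moments", {
  ## m = 5: E[D_2] = alpha_1 / sum(alpha) = 20 / (20 + 10 + 20/3 + 5)
  set.seed(52)
  d2 <- replicate(2e4, incorporation_schedule(5)[2])
  expected <- 20 / (20 + 10 + 20 / 3 + 5)
  expect_equal(expected, 0.48, tolerance = 1e-2)
  expect_equal(mean(d2), expected, tolerance = 0.01)
})

test_that("condition effects resample the schedule tail only", {
  set.seed(53)
  base <- incorporation_schedule(4)
  ## no flags: identical schedule
  eff0 <- apply_condition_effect(base, effect_p = 0)
  expect_identical(eff0$schedule, base)
  expect_identical(eff0$z, rep(0L, 3))
  ## all flags: still zero at t = 0, nondecreasing, final saturation kept
  eff1 <- apply_condition_effect(base, effect_p = 1)
  expect_identical(eff1$z, rep(1L, 3))
  expect_equal(eff1$schedule[1], 0)
  expect_true(all(diff(eff1$schedule) >= 0))
  expect_equal(eff1$schedule[4], 1)
  ## a flag at the first positive time leaves nothing before it unchanged
  ## and (a.s.) changes the schedule from there on
  found <- FALSE
  for (s in 1:200) {
    set.seed(1000 + s)
    base <- incorporation_schedule(4)
    eff <- apply_condition_effect(base, effect_p = 0.5)
    if (identical(eff$z, c(1L, 0L, 0L))) {
      found <- TRUE
      expect_equal(eff$schedule[1], base[1])
      expect_false(isTRUE(all.equal(eff$schedule[2:3], base[2:3])))
      expect_equal(eff$realized[1], 1L)
      break
    }
  }
  expect_true(found)
})

test_that("effect indicators are Bernoulli(0.05) and final-time flags are silent", {
  set.seed(54)
  zs <- replicate(3e4, apply_condition_effect(c(0, 0.4, 0.7, 1))$z[1])
  expect_equal(mean(zs == 0), 0.95, tolerance = 0.01)
  ## a flag at the last time point cannot alter a saturated schedule
  for (s in 1:100) {
    set.seed(2000 + s)
    base <- incorporation_schedule(4)
    eff <- apply_condition_effect(base, effect_p = 0.5)
    if (identical(eff$z, c(0L, 0L, 1L))) {
      expect_identical(eff$schedule, base)
      expect_equal(eff$realized[3], 0L)
    }
  }
})

test_that("simulated spectra shift their centroid by the incorporated mass", {
  seqr <- "GAMKLVSTYE"
  nex <- exchangeable_sites(seqr)
  set.seed(55)
  c0 <- mean(replicate(40, centroid(simulate_spectrum(seqr, 0, charge = 2,
                                                      n_ions = 5000))))
  c1 <- mean(replicate(40, centroid(simulate_spectrum(seqr, 1, charge = 2,
                                                      n_ions = 5000))))
  ch <- mean(replicate(40, centroid(simulate_spectrum(seqr, 0.5, charge = 2,
                                                      n_ions = 5000))))
  expect_equal(c1 - c0, nex * 1.00628, tolerance = 0.01)
  expect_equal(ch - c0, 0.5 * nex * 1.00628, tolerance = 0.02)
  ## undeuterated centroid sits just above the monoisotopic peptide mass
  ## (natural heavy-isotope envelope), within a Dalton
  aa <- strsplit(seqr, "")[[1]]
  mono <- sum(c(G = 57.02146, A = 71.03711, M = 131.04049, K = 128.09496,
                L = 113.08406, V = 99.06841, S = 87.03203, T = 101.04768,
                Y = 163.06333, E = 129.04259)[aa]) + 18.010565
  expect_gt(c0, mono)
  expect_lt(c0 - mono, 1)
})

test_that("simulate_dataset produces the full design with consistent truth", {
  cfg <- sim_config("A", n_peptides = 5, seed = 56)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$data), 5 * 4 * 3 * 2)
  expect_setequal(unique(sim$data$condition), c("C1", "C2"))
  expect_equal(nrow(sim$truth), 5 * 3)      # indicators at times 2..4
  expect_equal(nrow(sim$labels), 5)
  ## labels consistent with indicators
  agg <- aggregate(cbind(z, realized) ~ peptide, sim$truth, max)
  expect_equal(sim$labels$label_drawn,
               agg$z[match(sim$labels$peptide, agg$peptide)])
  expect_equal(sim$labels$label,
               agg$realized[match(sim$labels$peptide, agg$peptide)])
  ## label = 0 peptides have identical schedules in both conditions
  for (i in which(sim$labels$label == 0))
    expect_equal(sim$schedules[[i]][[1]], sim$schedules[[i]][[2]])
  ## residue spans match sequence lengths
  expect_equal(nchar(sim$data$sequence),
               sim$data$end - sim$data$start + 1L)
})

test_that("the generator is deterministic and round-trips the data module", {
  s1 <- simulate_dataset(sim_config("B", n_peptides = 3, seed = 57))
  s2 <- simulate_dataset(sim_config("B", n_peptides = 3, seed = 57))
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth, s2$truth)
  path <- withr::local_tempfile(fileext = ".csv")
  write_uptake_csv(s1$data, path)
  back <- normalize_uptake(read_uptake_csv(path))
  direct <- normalize_uptake(s1$data)
  expect_equal(back$uptake_da, direct$uptake_da, tolerance = 1e-9)
})

test_that("uptake curves are nondecreasing in expectation", {
  sim <- simulate_dataset(sim_config("A", n_peptides = 8, seed = 58))
  nd <- normalize_uptake(sim$data)
  agg <- aggregate(uptake_da ~ peptide + condition + time_s, nd, mean)
  for (pep in unique(agg$peptide)) for (cc in c("C1", "C2")) {
    u <- agg$uptake_da[agg$peptide == pep & agg$condition == cc]
    u <- u[order(agg$time_s[agg$peptide == pep & agg$condition == cc])]
    expect_true(all(diff(u) > -0.2))  # monotone up to centroid noise
  }
})
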