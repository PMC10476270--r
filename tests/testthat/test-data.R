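test_that("centroid implements the intensity-weighted neutral-mass convention", {
  p <- 1.007276
  d1 <- isotope_distribution(100.0, 1.0, charge = 1)
  expect_equal(centroid(d1), 100.0 - p)
  d2 <- isotope_distribution(c(100.0, 101.0), c(1, 1), charge = 1)
  expect_equal(centroid(d2, charge_correct = FALSE), 100.5)
  d3 <- isotope_distribution(c(500.0, 500.5), c(1, 1), charge = 2)
  expect_equal(centroid(d3), 2 * 500.25 - 2 * p)
  expect_equal(centroid(d3), 998.48544, tolerance = 1e-7)
})

test_that("centroid is invariant under uniform intensity scaling", {
  set.seed(1)
  for (k in c(0.01, 3, 1e4)) {
    mz <- sort(runif(7, 400, 410))
    int <- runif(7)
    d <- isotope_distribution(mz, int, charge = 2)
    dk <- isotope_distribution(mz, k * int, charge = 2)
    expect_equal(centroid(d), centroid(dk))
  }
})

test_that("invalid isotope distributions are rejected with named errors", {
  expect_error(isotope_distribution(c(100, 101), c(0, 0)), "all intensities zero")
  expect_error(isotope_distribution(c(100, 101), c(1, -1)), "negative intensity")
  expect_error(isotope_distribution(c(101, 100), c(1, 1)), "strictly increasing")
  expect_error(isotope_distribution(100, Inf), "non-finite")
})

test_that("normalize_uptake subtracts the time-zero reference per replicate", {
  df <- data.frame(peptide = "p1", condition = "A",
                   replicate = rep(1:2, each = 2),
                   time_s = c(0, 60, 0, 60),
                   centroid_mass = c(1000.0, 1002.5, 1000.2, 1002.2))
  out <- normalize_uptake(df)
  expect_equal(out$uptake_da, c(0, 2.5, 0, 2.0))
  ## all centroids equal -> all uptake zero
  df$centroid_mass <- 1000
  expect_equal(normalize_uptake(df)$uptake_da, rep(0, 4))
})

test_that("per-replicate referencing subtracts each replicate's own t0", {
  df <- data.frame(peptide = "p1", condition = "A",
                   replicate = rep(1:2, each = 2),
                   time_s = c(0, 60, 0, 60),
                   centroid_mass = c(1000.0, 1002.0, 1000.2, 1002.2))
  out <- normalize_uptake(df, reference = "replicate")
  expect_equal(out$uptake_da[df$time_s == 60], c(2.0, 2.0))
  expect_equal(unname(attr(out, "reference")), "replicate")
})

test_that("normalize_uptake is idempotent and errors on missing t0", {
  df <- make_series(seed = 5)
  once <- normalize_uptake(df)
  expect_identical(normalize_uptake(once)$uptake_da, once$uptake_da)
  bad <- data.frame(peptide = "p1", condition = "A", replicate = 1,
                    time_s = c(30, 60), centroid_mass = c(1, 2))
  expect_error(normalize_uptake(bad), "t = 0")
  ## pooled fallback when one replicate lacks its own t0
  df2 <- data.frame(peptide = "p1", condition = "A", replicate = c(1, 1, 2),
                    time_s = c(0, 60, 60),
                    centroid_mass = c(1000, 1002, 1003))
  out2 <- normalize_uptake(df2)
  expect_equal(unname(attr(out2, "reference")), "pooled")
  expect_error(normalize_uptake(df2, reference = "replicate"),
               "A/2")
})

test_that("fd_normalize computes fractional uptake and flags excess", {
  df <- data.frame(peptide = "p1", condition = "A", replicate = 1,
                   time_s = c(0, 30, 60), uptake_da = c(0, 2, 5))
  fd <- data.frame(peptide = "p1", fd_da = 4)
  expect_warning(out <- fd_normalize(df, fd), "exceed 1.2")
  expect_equal(out$uptake_frac, c(0, 0.5, 1.25))
  expect_equal(out$fd_flag, c(FALSE, FALSE, TRUE))
  expect_error(fd_normalize(df, data.frame(peptide = "p1", fd_da = 0)),
               "positive")
  expect_error(fd_normalize(df, data.frame(peptide = "q", fd_da = 1)),
               "no fully deuterated control")
})

test_that("uptake CSV round-trips through write/read", {
  sim <- simulate_dataset(sim_config("A", n_peptides = 3, seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_uptake_csv(sim$data, path)
  back <- read_uptake_csv(path)
  expect_equal(nrow(back), nrow(sim$data))
  expect_equal(back$centroid_mz, sim$data$centroid_mz, tolerance = 1e-9)
  expect_identical(back$peptide, sim$data$peptide)
  expect_identical(back$sequence, sim$data$sequence)
  ## normalization applies cleanly to read-back data
  nd <- normalize_uptake(back)
  expect_true(all(nd$uptake_da[nd$time_s == 0] == 0))
})

test_that("schema violations are reported by column name", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(peptide = "p", replicate = 1, time_s = 0, uptake_da = 0)
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_uptake_csv(path), "condition")
  df2 <- data.frame(peptide = "p", condition = "A", replicate = 1,
                    time_s = "soon", uptake_da = 0)
  utils::write.csv(df2, path, row.names = FALSE)
  expect_error(read_uptake_csv(path), "time")
})

test_that("duplicate rows error by default and can be averaged", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(peptide = "p", condition = "A", replicate = 1,
                   time_s = c(0, 0, 30), uptake_da = c(0, 0.2, 2))
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_uptake_csv(path), "duplicate")
  out <- read_uptake_csv(path, duplicates = "average")
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$uptake_da), c(0.1, 2))
})

test_that("minimal two-row CSV yields one peptide series of two records", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(peptide = "p", condition = "A", replicate = 1,
                   time_s = c(0, 30), uptake_da = c(0, 1.5))
  utils::write.csv(df, path, row.names = FALSE)
  out <- read_uptake_csv(path)
  ser <- peptide_series(out, "p")
  expect_equal(nrow(ser), 2)
  expect_error(peptide_series(out, "nope"), "unknown peptide")
})
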