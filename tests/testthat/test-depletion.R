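test_that("noiseless exponential depletion is recovered exactly", {
  # generating rate chosen so 1000 k / 0.33 = 33.2 uL/min/mg
  k <- 0.010956
  times <- c(0, 7, 17, 30, 60)
  ds <- depletion_dataset(times, 100 * exp(-k * times), protein_conc = 0.33)
  est <- fit_depletion_slope(ds)
  expect_equal(est$slope, k, tolerance = 1e-10)
  expect_equal(est$clint, 1000 * k / 0.33, tolerance = 1e-10)
  expect_equal(signif(est$clint, 3), 33.2)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
})

test_that("flat 100% time course gives zero slope and zero CLint", {
  ds <- depletion_dataset(c(0, 7, 17, 30, 60), rep(100, 5),
                          protein_conc = 0.5)
  est <- fit_depletion_slope(ds)
  expect_equal(est$slope, 0, tolerance = 1e-12)
  expect_equal(est$clint, 0, tolerance = 1e-12)
})

test_that("CLint formula: 1000 x slope / P, linear in slope, inverse in P", {
  expect_equal(signif(clint_from_slope(0.010956, 0.33), 3), 33.2)
  expect_equal(signif(clint_from_slope(0.0053, 0.5), 3), 10.6)
  expect_identical(clint_from_slope(0, 2), 0)
  set.seed(42)
  for (i in 1:25) {
    s <- runif(1, 0, 0.05); p <- runif(1, 0.1, 2); a <- runif(1, 0.5, 3)
    expect_equal(clint_from_slope(a * s, p), a * clint_from_slope(s, p))
    expect_equal(clint_from_slope(s, a * p), clint_from_slope(s, p) / a)
  }
  expect_error(clint_from_slope(0.01, 0), "protein_conc")
})

test_that("noisy depletion refit lands within 15% of truth (median)", {
  errs <- vapply(1:100, function(s) {
    ds <- gen_depletion(33.2, 0.33, noise_cv = 0.05, seed = s)
    abs(fit_depletion_slope(ds)$clint - 33.2) / 33.2
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("pooling is the unweighted mean, permutation-invariant, bounded", {
  vals <- c(33.2, 12.9, 34.0, 10.6, 10.3, 44.2)
  expect_equal(signif(pool_clint(vals), 3), 24.2)
  expect_identical(pool_clint(c(10, 10, 10)), 10)
  set.seed(7)
  for (i in 1:10) {
    x <- runif(sample(2:8, 1), 1, 100)
    expect_equal(pool_clint(x), sum(x) / length(x))
    expect_equal(pool_clint(sample(x)), pool_clint(x))
    expect_gte(pool_clint(x), min(x))
    expect_lte(pool_clint(x), max(x))
  }
  expect_error(pool_clint(numeric(0)), "empty")
})

test_that("pooling accepts clint_estimate objects", {
  ests <- lapply(c(0.010956, 0.0053), function(k) {
    t <- c(0, 10, 20, 40)
    fit_depletion_slope(depletion_dataset(t, 100 * exp(-k * t), 0.5))
  })
  expect_equal(pool_clint(ests), mean(1000 * c(0.010956, 0.0053) / 0.5),
               tolerance = 1e-8)
})

test_that("dataset invariants are enforced", {
  expect_error(depletion_dataset(c(0, 10), c(100, 50), 0.5), "3 time points")
  expect_error(depletion_dataset(c(1, 10, 20), c(100, 50, 20), 0.5),
               "first sampling time")
  expect_error(depletion_dataset(c(0, 10, 20), c(100, -5, 20), 0.5),
               "positive")
  expect_error(depletion_dataset(c(0, 20, 10), c(100, 50, 20), 0.5),
               "increasing")
})

test_that("depletion reader parses metadata and averages replicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# protein_conc_mg_ml: 0.33", "# substrate_uM: 1",
               "time_min\tremaining_pct\treplicate",
               "0\t100\t1", "0\t100\t2",
               "10\t80\t1", "10\t90\t2",
               "30\t50\t1", "30\t60\t2"), f)
  ds <- read_depletion(f)
  expect_equal(ds$protein_conc, 0.33)
  expect_equal(ds$substrate_conc, 1)
  expect_equal(ds$remaining, c(100, 85, 55))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_min\tremaining_pct", "0\t100"), f2)
  expect_error(read_depletion(f2), "protein_conc_mg_ml")
})
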