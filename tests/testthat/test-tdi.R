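test_that("inactivation rate: saturable in the inhibitor concentration", {
  expect_identical(inactivation_rate(0, 0.558, 5.8), 0)
  expect_equal(inactivation_rate(1e9, 0.558, 5.8), 0.558, tolerance = 1e-6)
  expect_equal(inactivation_rate(5.8, 0.558, 5.8), 0.558 / 2)
  expect_identical(inactivation_rate(0, 0.5, 0), 0)
})

test_that("enzyme turnover reaches the closed-form steady state", {
  kdeg <- 0.0193
  kapp_u <- 6.74 * 0.863
  lam <- inactivation_rate(1, 0.558, kapp_u)
  expect_equal(round(lam, 4), 0.0819)
  ss <- enzyme_steady_state(kdeg, lam)
  expect_equal(round(ss, 3), 0.191)
  sol <- simulate_enzyme(function(t) 1, kdeg, 0.558, kapp_u, t_end_h = 600)
  expect_equal(utils::tail(sol$e_active, 1), ss, tolerance = 1e-3)
})

test_that("no inhibitor means no inactivation; washout recovers at kdeg", {
  sol0 <- simulate_enzyme(function(t) 0, 0.02, 0.558, 5.8, t_end_h = 100)
  expect_equal(sol0$e_active, rep(1, nrow(sol0)), tolerance = 1e-9)
  # suppress to 0.4, then washout: E(t) = 1 - 0.6 exp(-kdeg t)
  kdeg <- 0.03
  sol <- simulate_enzyme(function(t) 0, kdeg, 0.558, 5.8, t_end_h = 80,
                         e0 = 0.4)
  expect_equal(sol$e_active, 1 - 0.6 * exp(-kdeg * sol$time_h),
               tolerance = 1e-6)
})

test_that("static AUC ratio formula and its limits", {
  expect_equal(round(static_auc_ratio(0.9, 0.5), 3), 1.818)
  expect_equal(static_auc_ratio(0, 0.5, 0.6, 0.9), 1.5)
  expect_equal(static_auc_ratio(0.7, 1), 1)
  expect_error(static_auc_ratio(1.2, 0.5), "fm")
})

test_that("a non-inactivating perpetrator leaves victim exposure unchanged", {
  p <- pip(); p$kinact <- 0; p$kapp <- 0
  r <- cosimulate_ddi(p, toy_victim(),
                      perp_schedule = dose_schedule(20, n_doses = 2,
                                                    interval_h = 24),
                      window_h = 48, output_step_h = 0.1)
  expect_equal(r$auc_ratio, 1, tolerance = 1e-6)
  expect_equal(r$cmax_ratio, 1, tolerance = 1e-6)
})

test_that("dynamic AUC ratio matches the static oracle at steady state", {
  # near-constant perpetrator exposure: small frequent doses for 3 weeks
  sched <- dose_schedule(20 / 12, n_doses = 12 * 21, interval_h = 2)
  vic <- toy_victim(fm = 0.9, clint_gut_u = 0)
  vic$dose_mg <- 10
  r <- cosimulate_ddi(pip(), vic, perp_schedule = sched,
                      window_h = 72, output_step_h = 0.1)
  e_at_dose <- r$enzyme$e_liver[which.min(abs(r$enzyme$time_h -
                                                r$window[1]))]
  expect_equal(r$auc_ratio, static_auc_ratio(0.9, e_at_dose),
               tolerance = 0.01)
})

test_that("AUC ratio grows with inactivation potency and perpetrator dose", {
  vic <- toy_victim(fm = 0.9, clint_gut_u = 10)
  sched3 <- dose_schedule(20, n_doses = 3, interval_h = 24)
  run <- function(kinact = 0.558, dose = 20, v = vic) {
    perp <- pip(); perp$kinact <- kinact
    s <- sched3; s$dose_mg <- dose
    cosimulate_ddi(perp, v, perp_schedule = s, window_h = 72,
                   output_step_h = 0.2)$auc_ratio
  }
  r_mid <- run()
  expect_gt(r_mid, run(kinact = 0.1))
  expect_lt(r_mid, run(kinact = 2))
  expect_gt(r_mid, run(dose = 5))
  expect_lt(r_mid, run(dose = 80))
  expect_gt(r_mid, run(v = toy_victim(fm = 0.5, clint_gut_u = 10)))
  expect_gt(r_mid, run(v = toy_victim(fm = 0.9, clint_gut_u = 0)))
})

test_that("victim ranking: simvastatin strongest, carbamazepine weakest", {
  tab <- ddi_table()
  expect_equal(tab$victim[which.max(tab$auc_ratio)], "simvastatin")
  expect_equal(tab$victim[which.min(tab$auc_ratio)], "carbamazepine")
  expect_true(all(tab$auc_ratio > 1))
})

test_that("Cmax ratios never exceed AUC ratios for the oral victims", {
  tab <- ddi_table()
  expect_true(all(tab$cmax_ratio <= tab$auc_ratio + 1e-9))
})
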