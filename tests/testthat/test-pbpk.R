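# engine-level checks: conservation, closed forms, linearity, NCA

test_that("mass is conserved with all clearances disabled", {
  p <- pip()
  p$clint_hlm <- NA_real_; p$clint_liver_u <- 0
  m <- build_model(p, phys(), dose_schedule(20, n_doses = 3,
                                            interval_h = 24))
  prof <- simulate_pk(m, t_end_h = 72)
  bal <- attr(prof, "balance")[[1]]
  expect_equal(bal$in_system, bal$dosed, tolerance = 1e-6)
  expect_equal(max(bal$eliminated), 0, tolerance = 1e-8)
})

test_that("mass balance holds to 0.1% with elimination active", {
  prof <- pip_week()
  bal <- attr(prof, "balance")[[1]]
  recon <- bal$in_system + bal$eliminated + bal$gut_metabolized
  i <- bal$dosed > 0
  expect_lt(max(abs(recon[i] - bal$dosed[i]) / bal$dosed[i]), 1e-3)
})

test_that("with extraction disabled the profile matches the Bateman form", {
  p <- pip()
  V <- p$vss * 70
  clint_u <- hepatic_clint_u(p)
  fu_b <- p$fu_plasma / p$bp_ratio
  cl_b <- well_stirred_clh(90, fu_b, clint_u)$clh
  ke <- cl_b * p$bp_ratio / V          # plasma clearance over volume
  ka <- ka_from_peff(p$peff_man)
  m <- build_model(p, phys(), dose_schedule(20), first_pass = FALSE,
                   absorption = "systemic")
  prof <- simulate_pk(m, t_end_h = 24)
  bateman <- 20 / V * ka / (ka - ke) *
    (exp(-ke * prof$time_h) - exp(-ka * prof$time_h)) * 1000
  i <- bateman > max(bateman) * 1e-3   # skip the t=0 zero crossing
  expect_lt(max(abs(prof$conc_ng_ml[i] - bateman[i]) / bateman[i]), 1e-3)
})

test_that("the model is linear: doubling dose doubles every concentration", {
  p1 <- simulate_pk(build_model(pip(), phys(), dose_schedule(20)),
                    t_end_h = 24)
  p2 <- simulate_pk(build_model(pip(), phys(), dose_schedule(40)),
                    t_end_h = 24)
  expect_equal(p2$conc_ng_ml, 2 * p1$conc_ng_ml, tolerance = 1e-6)
})

test_that("zero dose gives an identically zero profile", {
  prof <- simulate_pk(build_model(pip(), phys(), dose_schedule(0)),
                      t_end_h = 12)
  expect_true(all(prof$conc_ng_ml == 0))
})

test_that("multiple dosing obeys superposition in the linear model", {
  prof7 <- pip_week()
  prof1 <- pip_single()
  single <- simulate_pk(build_model(pip(), phys(), dose_schedule(20)),
                        t_end_h = 168)
  f <- stats::approxfun(single$time_h, single$conc_ng_ml, yleft = 0,
                        rule = 2)
  super <- Reduce(`+`, lapply(0:6 * 24, function(s)
    ifelse(prof7$time_h >= s, f(prof7$time_h - s), 0)))
  i <- super > max(super) * 0.01
  expect_lt(max(abs(prof7$conc_ng_ml[i] - super[i]) / super[i]), 5e-3)
  expect_equal(prof1$conc_ng_ml,
               single$conc_ng_ml[single$time_h <= 24], tolerance = 1e-8)
})

test_that("steady-state accumulation matches 1/(1 - exp(-ke tau))", {
  # fast absorption relative to the 24 h interval
  p <- compound_params("fastabs", mw = 300, compound_type = "neutral",
                       bp_ratio = 1, fu_plasma = 0.1, vss = 0.8,
                       clint_liver_u = 35, ka = 10, dose_mg = 10)
  sched <- dose_schedule(10, n_doses = 14, interval_h = 24)
  prof <- simulate_pk(build_model(p, phys(), sched), t_end_h = 14 * 24)
  auc1 <- nca(prof, c(0, 24))$auc_last
  aucss <- nca(prof, c(13 * 24, 14 * 24))$auc_last
  cl_b <- well_stirred_clh(90, 0.1, 35)$clh
  ke <- cl_b / (0.8 * 70)
  expect_equal(aucss / auc1, 1 / (1 - exp(-ke * 24)), tolerance = 0.01)
})

test_that("NCA: trapezoid AUC against the analytic Bateman area", {
  p <- pip()
  m <- build_model(p, phys(), dose_schedule(20), first_pass = FALSE,
                   absorption = "systemic")
  prof <- simulate_pk(m, t_end_h = 120)
  met <- nca(prof)
  V <- p$vss * 70
  cl_p <- well_stirred_clh(90, p$fu_plasma / p$bp_ratio,
                           hepatic_clint_u(p))$clh * p$bp_ratio
  expect_equal(met$auc_last, 20 / cl_p * 1000, tolerance = 5e-3)
})

test_that("NCA handles flat and degenerate windows", {
  prof <- data.frame(time_h = 0:10, conc_ng_ml = rep(7, 11))
  expect_equal(nca(prof, c(0, 10))$auc_last, 70)
  expect_equal(nca(prof, c(3, 3))$auc_last, 0)
  expect_error(nca(prof, c(20, 30)), "empty")
})

test_that("halving the output step changes NCA metrics by < 0.1%", {
  m <- build_model(pip(), phys(), dose_schedule(20))
  a <- nca(simulate_pk(m, t_end_h = 24, output_step_h = 0.05))
  b <- nca(simulate_pk(m, t_end_h = 24, output_step_h = 0.025))
  expect_equal(a$cmax, b$cmax, tolerance = 1e-3)
  expect_equal(a$auc_last, b$auc_last, tolerance = 1e-3)
})
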