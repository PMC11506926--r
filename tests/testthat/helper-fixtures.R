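# Shared fixtures.  Expensive whole-pipeline simulations are memoised so
# interaction properties and model-validation checks reuse one run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

pip <- function() memo("pip", piperine_params())
phys <- function() memo("phys", physiology())

# ten-victim interaction table under the reference (no-variability) design:
# 20 mg/day piperine x 7, victim dosed with the last piperine dose
ddi_table <- function() memo("ddi_table", {
  rows <- lapply(victim_fixtures(phys()), function(v) {
    r <- cosimulate_ddi(pip(), v, phys())
    data.frame(victim = r$victim, auc_ratio = r$auc_ratio,
               cmax_ratio = r$cmax_ratio)
  })
  do.call(rbind, rows)
})

# piperine single- and multiple-dose reference simulations
pip_single <- function() memo("pip_single", {
  simulate_pk(build_model(pip(), phys(), dose_schedule(20)), t_end_h = 24)
})
pip_week <- function() memo("pip_week", {
  sched <- dose_schedule(20, n_doses = 7, interval_h = 24)
  simulate_pk(build_model(pip(), phys(), sched), t_end_h = 168)
})

# a fast synthetic low-extraction victim for closed-form interaction checks
toy_victim <- function(fm = 0.9, clint_gut_u = 0) {
  compound_params(name = "probe", mw = 300, compound_type = "neutral",
                  bp_ratio = 1, fu_plasma = 0.1, fu_gut = 1, qgut = 15.7,
                  vss = 0.7, clint_liver_u = 60, fm_cyp3a4 = fm,
                  clint_gut_u = clint_gut_u, ka = 3, dose_mg = 10)
}
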