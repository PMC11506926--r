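#' Mechanism-based inactivation rate
#'
#' `lambda = kinact * Iu / (Kapp_u + Iu)` — the saturable first-order rate
#' at which unbound inactivator irreversibly removes active enzyme.
#' `Kapp_u` is the unbound apparent half-maximal inactivator concentration
#' (`kapp * fu_mic`).
#'
#' @param i_u unbound inactivator concentration at the enzyme site, uM
#' @param kinact maximal inactivation rate constant, 1/h
#' @param kapp_u unbound half-maximal inactivator concentration, uM
#' @return inactivation rate, 1/h
#' @export
inactivation_rate <- function(i_u, kinact, kapp_u) {
  if (any(i_u < 0) || kinact < 0 || kapp_u < 0)
    stop("inactivation inputs must be non-negative")
  ifelse(kapp_u + i_u == 0, 0, kinact * i_u / (kapp_u + i_u))
}

#' Active-enzyme steady state under constant inactivator
#'
#' Closed form of `dE/dt = kdeg (1 - E) - lambda E`:
#' `E_ss = kdeg / (kdeg + lambda)`.
#'
#' @param kdeg enzyme degradation rate constant, 1/h
#' @param lambda inactivation rate, 1/h
#' @return steady-state active fraction of baseline enzyme
#' @export
enzyme_steady_state <- function(kdeg, lambda) {
  stopifnot(kdeg > 0, lambda >= 0)
  kdeg / (kdeg + lambda)
}

#' Integrate enzyme turnover under a prescribed inactivator exposure
#'
#' Solves `dE/dt = kdeg (1 - E) - lambda(Iu(t)) E` with `E(0) = e0` for an
#' arbitrary unbound-inactivator time course, independently of the PK
#' engine (used for closed-form verification and washout analyses).
#'
#' @param i_u_fun function of time (h) returning unbound inactivator uM
#' @param kdeg degradation rate constant, 1/h
#' @param kinact,kapp_u inactivation constants (see [inactivation_rate()])
#' @param t_end_h,output_step_h time grid
#' @param e0 initial active fraction
#' @return data.frame with `time_h`, `e_active`
#' @export
simulate_enzyme <- function(i_u_fun, kdeg, kinact, kapp_u,
                            t_end_h = 240, output_step_h = 0.1, e0 = 1) {
  stopifnot(kdeg > 0)
  rhs <- function(t, y, p) {
    lam <- inactivation_rate(i_u_fun(t), kinact, kapp_u)
    list(kdeg * (1 - y[1]) - lam * y[1])
  }
  out <- deSolve::lsoda(c(e = e0), seq(0, t_end_h, output_step_h), rhs,
                        NULL, rtol = 1e-10, atol = 1e-12)
  data.frame(time_h = out[, "time"], e_active = out[, "e"])
}

#' Static mechanistic AUC ratio
#'
#' Closed-form oracle for a low-extraction victim under steady-state
#' inactivation: `AUCR = (Fg_inhibited / Fg_alone) *
#' 1 / (fm * E_liver_ss + (1 - fm))`.
#'
#' @param fm fraction of the victim's clearance via CYP3A4
#' @param e_liver_ss steady-state active hepatic enzyme fraction
#' @param fg_alone,fg_inhibited intestinal availability without / with the
#'   perpetrator
#' @return predicted AUC ratio (with/without perpetrator)
#' @examples
#' static_auc_ratio(0.9, 0.5)  # 1.818
#' @export
static_auc_ratio <- function(fm, e_liver_ss, fg_alone = 1,
                             fg_inhibited = fg_alone) {
  if (fm < 0 || fm > 1) stop("fm must lie in [0, 1]")
  stopifnot(e_liver_ss > 0, e_liver_ss <= 1, fg_alone > 0, fg_alone <= 1,
            fg_inhibited > 0, fg_inhibited <= 1)
  (fg_inhibited / fg_alone) / (fm * e_liver_ss + (1 - fm))
}

#' Co-simulate a victim drug with and without the perpetrator
#'
#' Runs the joint PBPK/enzyme-turnover system twice — victim alone and
#' victim with the perpetrator dosing regimen — and reports exposure
#' ratios.  The victim's hepatic CYP3A4-mediated intrinsic clearance is
#' scaled by the active hepatic enzyme fraction `E_liver(t)` (the
#' remaining `1 - fm` share is untouched) and its gut intrinsic clearance
#' by `E_gut(t)`.  The hepatic inactivation driver is the unbound
#' perpetrator concentration at the liver inlet (systemic blood plus
#' portal absorption flux over hepatic flow); the intestinal driver is the
#' perpetrator enterocyte concentration.
#'
#' By default the victim single dose is given together with the last
#' perpetrator dose, and exposure is read over `window_h` hours from the
#' victim dose.
#'
#' @param perpetrator,victim [compound_params()] objects; the victim needs
#'   `fm_cyp3a4` and gut parameters, the perpetrator its TDI constants
#' @param physiology a [physiology()] object
#' @param perp_schedule perpetrator regimen (default 20 mg/day x 7)
#' @param victim_schedule victim regimen (default: single `dose_mg` with
#'   the last perpetrator dose)
#' @param window_h length of the victim observation window, h
#' @param output_step_h integration output step, h
#' @param ... further options passed to [build_model()] (e.g.
#'   `gut_driver`, `abundance_mult`, `kdeg_mult`)
#' @return an object of class `interaction_result`: AUC and Cmax for both
#'   arms, their ratios, and the enzyme trajectories of the interaction
#'   arm
#' @export
cosimulate_ddi <- function(perpetrator, victim,
                           physiology = piperpbpk::physiology(),
                           perp_schedule = dose_schedule(20, n_doses = 7,
                                                         interval_h = 24),
                           victim_schedule = NULL,
                           window_h = 168, output_step_h = 0.05, ...) {
  if (victim$fm_cyp3a4 <= 0 && victim$clint_gut_u == 0)
    stop("victim has no CYP3A4-mediated pathway (fm_cyp3a4 missing)")
  if (is.null(victim_schedule)) {
    if (is.na(victim$dose_mg)) stop("victim dose_mg missing")
    victim_schedule <- dose_schedule(victim$dose_mg,
                                     start_h = max(dose_times(perp_schedule)))
  }
  t_vic <- min(dose_times(victim_schedule))
  t_end <- max(dose_times(victim_schedule)) + window_h
  run <- function(perp_dose) {
    ps <- perp_schedule
    ps$dose_mg <- perp_dose
    m <- build_model(victim, physiology, victim_schedule,
                     perpetrator = perpetrator, perpetrator_schedule = ps,
                     ...)
    simulate_pk(m, t_end_h = t_end, output_step_h = output_step_h)
  }
  alone <- run(0)
  with_p <- run(perp_schedule$dose_mg)
  w <- c(t_vic, t_vic + window_h)
  m_alone <- nca(alone, w)
  m_with <- nca(with_p, w)
  structure(list(victim = victim$name, perpetrator = perpetrator$name,
                 auc_alone = m_alone$auc_last, auc_with = m_with$auc_last,
                 cmax_alone = m_alone$cmax, cmax_with = m_with$cmax,
                 auc_ratio = m_with$auc_last / m_alone$auc_last,
                 cmax_ratio = m_with$cmax / m_alone$cmax,
                 window = w,
                 enzyme = attr(with_p, "enzyme"),
                 profile_alone = as.data.frame(alone),
                 profile_with = as.data.frame(with_p)),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf(
    "<interaction_result> %s + %s\n  AUC  %8.4g -> %8.4g  ratio %.3f\n  Cmax %8.4g -> %8.4g  ratio %.3f\n",
    x$victim, x$perpetrator, x$auc_alone, x$auc_with, x$auc_ratio,
    x$cmax_alone, x$cmax_with, x$cmax_ratio))
  invisible(x)
}
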