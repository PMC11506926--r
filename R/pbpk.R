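# Reduced oral PBPK engine: gut lumen -> enterocyte (Qgut first pass) ->
# well-stirred liver (quasi-steady-state availability) -> systemic
# compartment sized by Vss, coupled to CYP3A4 active-enzyme turnover at the
# hepatic and intestinal expression sites.  Amounts in mg, times in h,
# concentrations reported as plasma ng/mL.

# resolve a compound into the constant block the ODE right-hand side uses
compile_compound <- function(compound, physiology, fu_mic_correction = TRUE,
                             renal = FALSE, abundance_mult = 1) {
  ka <- compound$ka
  if (is.na(ka)) {
    if (is.na(compound$peff_man))
      stop(compound$name, ": neither ka nor peff_man available")
    ka <- ka_from_peff(compound$peff_man, physiology$intestinal_radius_cm)
  }
  if (is.na(compound$vss))
    stop(compound$name, ": vss missing; supply it or predict it with ",
         "vss_method2()")
  fu_b <- blood_unbound_fraction(compound$fu_plasma, compound$bp_ratio)
  clint_u <- hepatic_clint_u(compound, physiology, fu_mic_correction)
  fm <- compound$fm_cyp3a4
  # CYP3A4 abundance scaling acts on the CYP3A4-mediated share only
  clint_gut_u <- compound$clint_gut_u * abundance_mult
  list(name = compound$name, mw = compound$mw, ka = ka,
       v = compound$vss * physiology$body_weight_kg,
       bp = compound$bp_ratio, fu_b = fu_b,
       clint_u_3a4 = clint_u * fm * abundance_mult,
       clint_u_other = clint_u * (1 - fm),
       qgut = compound$qgut, fu_gut = compound$fu_gut,
       clint_gut_u = clint_gut_u,
       cl_r = renal_clearance(fu_b, physiology$gfr, enabled = renal),
       kinact = compound$kinact,
       kapp_u = compound$kapp * compound$fu_mic)
}

#' Build a PBPK simulation model
#'
#' Assembles the ODE system for one or two orally dosed compounds sharing
#' the CYP3A4 enzyme pools.  States per compound: gut-lumen amount,
#' enterocyte amount, systemic amount, cumulative hepatic+renal
#' elimination, cumulative gut metabolism; plus the active-enzyme fractions
#' at liver and gut.  The liver is treated as an instantaneous well-stirred
#' extractor: portal inflow (Qgut x enterocyte concentration) and systemic
#' recirculation are cleared with a time-varying availability recomputed
#' from the active-enzyme-scaled intrinsic clearance at every step.
#'
#' @param compound a [compound_params()] object (the reported compound)
#' @param physiology a [physiology()] object
#' @param schedule a [dose_schedule()] for `compound`
#' @param perpetrator optional second compound acting on the shared CYP3A4
#'   pools (used by [cosimulate_ddi()])
#' @param perpetrator_schedule dosing schedule for the perpetrator
#' @param fu_mic_correction divide microsomal CLint by fu_mic (IVIVE)
#' @param renal enable filtration renal clearance for `compound`
#' @param auto_inhibition let the primary compound's own `fm_cyp3a4` couple
#'   its elimination to the enzyme state (off by default: the piperine
#'   input set does not assign its clearance to CYP3A4)
#' @param first_pass apply hepatic first-pass extraction to absorbed drug
#'   (disable only for closed-form verification)
#' @param absorption `"enterocyte"` routes absorbed drug through the
#'   enterocyte/Qgut first-pass path; `"systemic"` delivers it directly to
#'   the systemic compartment (closed-form verification)
#' @param gut_driver enterocyte inactivation driver: `"total"` (default,
#'   the conservative regulatory convention) or `"unbound"` (applies
#'   fu_gut)
#' @param abundance_mult,kdeg_mult subject-level CYP3A4 abundance and
#'   turnover multipliers (virtual population)
#' @return an object of class `pbpk_model`
#' @export
build_model <- function(compound, physiology = piperpbpk::physiology(),
                        schedule = dose_schedule(compound$dose_mg),
                        perpetrator = NULL, perpetrator_schedule = NULL,
                        fu_mic_correction = TRUE, renal = FALSE,
                        auto_inhibition = FALSE, first_pass = TRUE,
                        absorption = c("enterocyte", "systemic"),
                        gut_driver = c("total", "unbound"),
                        abundance_mult = 1, kdeg_mult = 1) {
  absorption <- match.arg(absorption)
  gut_driver <- match.arg(gut_driver)
  primary <- compound
  # a lone compound couples to its own enzyme pool only when auto-inhibition
  # is requested; with a separate perpetrator the primary is a victim and
  # its fm stays active
  if (is.null(perpetrator) && !auto_inhibition) primary$fm_cyp3a4 <- 0
  cmp <- list(compile_compound(primary, physiology, fu_mic_correction,
                               renal, abundance_mult))
  sched <- list(schedule)
  if (!is.null(perpetrator)) {
    if (is.null(perpetrator_schedule))
      stop("perpetrator_schedule required when perpetrator is given")
    cmp[[2]] <- compile_compound(perpetrator, physiology, fu_mic_correction,
                                 renal = FALSE, abundance_mult)
    sched[[2]] <- perpetrator_schedule
  }
  structure(list(compounds = cmp, schedules = sched, physiology = physiology,
                 first_pass = first_pass, absorption = absorption,
                 gut_driver = gut_driver,
                 kdeg_liver = physiology$kdeg_liver * kdeg_mult,
                 kdeg_gut = physiology$kdeg_gut * kdeg_mult),
            class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat("<pbpk_model>", paste(vapply(x$compounds, `[[`, "", "name"),
                            collapse = " + "), "\n")
  invisible(x)
}

# deSolve right-hand side shared by all simulations
pbpk_rhs <- function(t, y, m) {
  n <- length(m$compounds)
  e_liv <- y[5 * n + 1]
  e_gut <- y[5 * n + 2]
  dy <- numeric(length(y))
  lam_liv <- 0
  lam_gut <- 0
  v_ent <- m$physiology$enterocyte_volume_l
  q_h <- m$physiology$q_h
  for (i in seq_len(n)) {
    k <- 5 * (i - 1)
    cc <- m$compounds[[i]]
    a_lum <- y[k + 1]; a_ent <- y[k + 2]; a_sys <- y[k + 3]
    c_ent <- a_ent / v_ent
    c_p <- a_sys / cc$v
    c_b <- c_p * cc$bp
    clint_eff <- cc$clint_u_3a4 * e_liv + cc$clint_u_other
    fu_cl <- cc$fu_b * clint_eff
    e_h <- fu_cl / (q_h + fu_cl)
    gut_met <- cc$fu_gut * cc$clint_gut_u * e_gut * c_ent
    portal <- cc$qgut * c_ent
    abs_rate <- cc$ka * a_lum
    if (m$absorption == "enterocyte") {
      dy[k + 1] <- -abs_rate
      dy[k + 2] <- abs_rate - portal - gut_met
      inflow <- portal
    } else {
      dy[k + 1] <- -abs_rate
      dy[k + 2] <- 0
      inflow <- abs_rate
      portal <- abs_rate  # inactivation driver sees the absorbed flux
    }
    fh_in <- if (m$first_pass) 1 - e_h else 1
    dy[k + 3] <- fh_in * inflow - q_h * e_h * c_b - cc$cl_r * c_b
    dy[k + 4] <- (1 - fh_in) * inflow + q_h * e_h * c_b + cc$cl_r * c_b
    dy[k + 5] <- gut_met
    if (cc$kinact > 0) {
      # clamp: the integrator can probe infinitesimally negative amounts
      i_liv <- max(0, cc$fu_b * (c_b + portal / q_h) * 1000 / cc$mw)  # uM
      i_gut <- max(0, c_ent * 1000 / cc$mw)
      if (m$gut_driver == "unbound") i_gut <- i_gut * cc$fu_gut
      lam_liv <- lam_liv + inactivation_rate(i_liv, cc$kinact, cc$kapp_u)
      lam_gut <- lam_gut + inactivation_rate(i_gut, cc$kinact, cc$kapp_u)
    }
  }
  dy[5 * n + 1] <- m$kdeg_liver * (1 - e_liv) - lam_liv * e_liv
  dy[5 * n + 2] <- m$kdeg_gut * (1 - e_gut) - lam_gut * e_gut
  list(dy)
}

#' Simulate a PBPK model
#'
#' Integrates the model with a stiff-capable solver (lsoda, relative
#' tolerance 1e-8, absolute tolerance 1e-12 mg) on a dense fixed output
#' grid; doses are applied as state discontinuities at exact event times.
#'
#' @param model a [build_model()] object
#' @param t_end_h end of the simulation, h (default: covers the dosing
#'   schedule plus 24 h washout)
#' @param output_step_h output grid step, h
#' @return a `conc_profile` data.frame with columns `time_h` and
#'   `conc_ng_ml` (plasma concentration of the primary compound); the full
#'   state matrix, enzyme trajectories and mass-balance table are attached
#'   as attributes `states`, `enzyme`, `balance`.
#' @export
simulate_pk <- function(model, t_end_h = NULL, output_step_h = 0.05) {
  stopifnot(inherits(model, "pbpk_model"))
  n <- length(model$compounds)
  ev <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- model$schedules[[i]]
    data.frame(var = paste0("a_lum_", i), time = dose_times(s),
               value = s$dose_mg, method = "add")
  }))
  ev <- ev[ev$value > 0, , drop = FALSE]
  ev <- ev[order(ev$time), , drop = FALSE]
  if (is.null(t_end_h))
    t_end_h <- max(vapply(model$schedules, function(s)
      max(dose_times(s)), numeric(1))) + 24
  times <- seq(0, t_end_h, by = output_step_h)
  times <- sort(unique(c(times, ev$time[ev$time <= t_end_h])))
  y0 <- numeric(5 * n + 2)
  names(y0) <- c(paste0(rep(c("a_lum_", "a_ent_", "a_sys_", "a_elim_",
                              "a_gutx_"), n),
                        rep(seq_len(n), each = 5)), "e_liv", "e_gut")
  y0[c("e_liv", "e_gut")] <- 1
  out <- try(deSolve::lsoda(y0, times, pbpk_rhs, model,
                            events = if (nrow(ev)) list(data = ev),
                            rtol = 1e-8, atol = 1e-12, maxsteps = 50000),
             silent = TRUE)
  if (inherits(out, "try-error") ||
      nrow(out) < length(times))
    stop("integration failed: ", attr(out, "condition")$message %||%
           "incomplete output grid")
  prof <- data.frame(time_h = out[, "time"],
                     conc_ng_ml = out[, "a_sys_1"] /
                       model$compounds[[1]]$v * 1000)
  dosed <- vapply(seq_len(n), function(i) {
    s <- model$schedules[[i]]
    # states at event times are reported pre-event, so count doses strictly
    # before each output time
    vapply(out[, "time"], function(tt)
      s$dose_mg * sum(dose_times(s) < tt), numeric(1))
  }, numeric(nrow(out)))
  balance <- lapply(seq_len(n), function(i) {
    k <- 5 * (i - 1)
    data.frame(time_h = out[, "time"], dosed = dosed[, i],
               in_system = rowSums(out[, k + 1 + (1:3), drop = FALSE]),
               eliminated = out[, k + 5], gut_metabolized = out[, k + 6])
  })
  structure(prof, class = c("conc_profile", "data.frame"),
            states = out,
            enzyme = data.frame(time_h = out[, "time"],
                                e_liver = out[, "e_liv"],
                                e_gut = out[, "e_gut"]),
            balance = balance, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Non-compartmental summary of a concentration profile
#'
#' Cmax/Tmax from the grid maximum and AUC by the linear trapezoid rule on
#' the dense grid, over an observation window.
#'
#' @param profile a `conc_profile` (or any data.frame with `time_h`,
#'   `conc_ng_ml`)
#' @param window numeric length-2 `(t0, t1)` in h; default spans the grid
#' @return an object of class `pk_metrics`: `cmax` (ng/mL), `tmax` (h),
#'   `auc_last` (ng/mL h), `window`
#' @export
nca <- function(profile, window = NULL) {
  t <- profile$time_h; c <- profile$conc_ng_ml
  if (is.null(window)) window <- range(t)
  keep <- t >= window[1] & t <= window[2]
  if (!any(keep)) stop("empty observation window")
  t <- t[keep]; c <- c[keep]
  auc <- if (length(t) > 1)
    sum(diff(t) * (utils::head(c, -1) + utils::tail(c, -1)) / 2) else 0
  structure(list(cmax = max(c), tmax = t[which.max(c)], auc_last = auc,
                 window = window),
            class = "pk_metrics")
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf(
    "<pk_metrics> Cmax %.3g ng/mL at %.2f h; AUC(%g-%g h) %.4g ng/mL.h\n",
    x$cmax, x$tmax, x$window[1], x$window[2], x$auc_last))
  invisible(x)
}

#' Write a concentration profile as delimited text
#'
#' @param profile a `conc_profile`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile)[, c("time_h", "conc_ng_ml")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
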