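# Synthetic-data generators: every pipeline input can be produced with
# known ground truth, so each stage is testable by round trip.  All
# generators are pure functions of (parameters, seed); noise is
# multiplicative log-normal with median 1 (concentrations are positive and
# variability is naturally expressed as a CV).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

lognormal_noise <- function(n, cv) {
  if (cv < 0) stop("noise_cv must be non-negative")
  if (cv == 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Generate a microsomal substrate-depletion time course
#'
#' Mono-exponential depletion `remaining% = 100 exp(-k t)` with
#' `k = true_clint * P / 1000` (the inverse of the CLint formula),
#' multiplied by median-1 log-normal noise of the stated CV at every
#' sampled point except t = 0.
#'
#' @param true_clint generating intrinsic clearance, uL/min/mg protein
#' @param protein_conc microsomal protein, mg/mL
#' @param times sampling times, min (the standard depletion design samples
#'   0, 7, 17, 30 and 60 min)
#' @param noise_cv proportional noise CV (fraction)
#' @param seed RNG seed
#' @return a [depletion_dataset()]
#' @export
gen_depletion <- function(true_clint, protein_conc = 0.5,
                          times = c(0, 7, 17, 30, 60), noise_cv = 0,
                          seed = 1) {
  if (true_clint < 0) stop("true_clint must be non-negative")
  if (times[1] != 0) stop("times must include 0 first")
  k <- true_clint * protein_conc / 1000
  remaining <- 100 * exp(-k * times)
  noise <- with_seed(seed, lognormal_noise(length(times) - 1, noise_cv))
  remaining[-1] <- remaining[-1] * noise
  depletion_dataset(times, remaining, protein_conc)
}

#' Generate a synthetic "observed" plasma profile
#'
#' Simulates the compound under multiplicatively perturbed parameters,
#' adds proportional log-normal noise, and subsamples to a clinical-like
#' sparse sampling grid — a stand-in for digitized clinical
#' concentration-time data with known ground truth.
#'
#' @param compound a [compound_params()] object
#' @param physiology a [physiology()] object
#' @param schedule a [dose_schedule()]
#' @param param_perturbation named list of multiplicative factors applied
#'   to numeric compound fields (e.g. `list(clint_hlm = 0.5)`)
#' @param noise_cv proportional observation noise CV
#' @param seed RNG seed
#' @param sample_times_h sampling times after the first dose, h
#' @param ... passed to [build_model()]
#' @return a data.frame `time_h`, `conc_ng_ml` with attribute `truth`
#'   (the unperturbed dense prediction)
#' @export
gen_observed_profile <- function(compound,
                                 physiology = piperpbpk::physiology(),
                                 schedule = dose_schedule(compound$dose_mg),
                                 param_perturbation = list(),
                                 noise_cv = 0, seed = 1,
                                 sample_times_h = c(0.5, 1, 2, 3, 4, 6, 8,
                                                    12, 24), ...) {
  pert <- compound
  for (nm in names(param_perturbation)) {
    if (!nm %in% names(pert) || !is.numeric(pert[[nm]]))
      stop("unknown or non-numeric perturbation target: ", nm)
    pert[[nm]] <- pert[[nm]] * param_perturbation[[nm]]
  }
  validate_compound(pert)
  t_end <- max(dose_times(schedule)) + max(sample_times_h)
  prof <- simulate_pk(build_model(pert, physiology, schedule, ...),
                      t_end_h = t_end)
  tt <- min(dose_times(schedule)) + sample_times_h
  conc <- stats::approx(prof$time_h, prof$conc_ng_ml, tt)$y
  conc <- conc * with_seed(seed, lognormal_noise(length(conc), noise_cv))
  structure(data.frame(time_h = tt, conc_ng_ml = conc),
            truth = prof)
}

#' Bundled victim-drug parameter table
#'
#' @return the raw fixture table (data.frame), one row per victim
#' @seealso [victim_fixtures()]
#' @export
victim_table <- function() {
  utils::read.table(system.file("extdata", "victim_fixtures.tsv",
                                package = "piperpbpk"),
                    header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Ten CYP3A4 victim-drug parameter sets
#'
#' Builds [compound_params()] objects for the ten interaction victims from
#' the bundled literature-sourced fixture table (a documented synthetic
#' stand-in for proprietary platform compound files).  Hepatic unbound
#' intrinsic clearance is back-calculated from systemic plasma clearance
#' through the well-stirred model, and gut CYP3A4 intrinsic clearance from
#' the baseline intestinal availability through the Qgut relation
#' `Fg = Qgut / (Qgut + fu_gut * CLint_gut_u)` with `fu_gut = 1`.
#'
#' @param physiology a [physiology()] object (hepatic blood flow)
#' @return named list of `compound_params`
#' @export
victim_fixtures <- function(physiology = piperpbpk::physiology()) {
  tab <- victim_table()
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    cl_b <- r$cl_plasma_lh / r$bp_ratio
    fu_b <- r$fu_plasma / r$bp_ratio
    if (cl_b >= physiology$q_h)
      stop(r$name, ": blood clearance exceeds hepatic blood flow")
    clint_u <- physiology$q_h * cl_b / (fu_b * (physiology$q_h - cl_b))
    clint_gut_u <- r$qgut_lh * (1 / r$fg_baseline - 1)
    compound_params(name = r$name, mw = r$mw, compound_type = "neutral",
                    bp_ratio = r$bp_ratio, fu_plasma = r$fu_plasma,
                    fu_gut = 1, qgut = r$qgut_lh, vss = r$vss_lkg,
                    clint_liver_u = clint_u, fm_cyp3a4 = r$fm_cyp3a4,
                    clint_gut_u = clint_gut_u, ka = r$ka_h,
                    dose_mg = r$dose_mg)
  })
  names(out) <- tab$name
  out
}
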