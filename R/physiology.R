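#' System (physiology) parameters
#'
#' Container for the anatomical and enzyme-turnover constants used throughout
#' the pipeline.  Defaults are standard adult reference values from the
#' IVIVE/PBPK literature: 70 kg body weight, hematocrit 0.45, hepatic blood
#' flow 90 L/h, liver 1650 g with 40 mg microsomal protein per g liver
#' (MPPGL), small-intestinal radius 1.75 cm, villous blood flow 18 L/h, and
#' CYP3A4 turnover half-lives of ~36 h in liver (kdeg 0.0193 1/h) and ~23 h
#' in gut (kdeg 0.03 1/h).  Between-subject coefficients of variation for
#' CYP3A4 abundance (41%) and turnover (68%) parameterize the virtual
#' population.
#'
#' @param body_weight_kg body weight, kg
#' @param hematocrit volume fraction of erythrocytes in blood
#' @param q_h hepatic blood flow, L/h
#' @param liver_weight_g liver weight, g
#' @param mppgl mg microsomal protein per g liver
#' @param q_villi villous (mucosal) blood flow, L/h
#' @param intestinal_radius_cm effective small-intestinal radius, cm
#' @param gfr glomerular filtration rate, L/h
#' @param enterocyte_volume_l effective enterocyte distribution volume, L
#' @param kdeg_liver,kdeg_gut first-order CYP3A4 degradation rate constants,
#'   1/h, at the hepatic and intestinal expression sites
#' @param cv_abundance,cv_kdeg between-subject coefficients of variation
#'   (fractions) for CYP3A4 abundance and turnover
#' @param ph_plasma,ph_iw,ph_bc plasma, tissue-intracellular and
#'   erythrocyte-intracellular pH
#' @return an object of class `physiology` (a validated named list)
#' @export
physiology <- function(body_weight_kg = 70, hematocrit = 0.45, q_h = 90,
                       liver_weight_g = 1650, mppgl = 40, q_villi = 18,
                       intestinal_radius_cm = 1.75, gfr = 7.2,
                       enterocyte_volume_l = 1,
                       kdeg_liver = 0.0193, kdeg_gut = 0.03,
                       cv_abundance = 0.41, cv_kdeg = 0.68,
                       ph_plasma = 7.4, ph_iw = 7.0, ph_bc = 7.22) {
  p <- list(body_weight_kg = body_weight_kg, hematocrit = hematocrit,
            q_h = q_h, liver_weight_g = liver_weight_g, mppgl = mppgl,
            q_villi = q_villi, intestinal_radius_cm = intestinal_radius_cm,
            gfr = gfr, enterocyte_volume_l = enterocyte_volume_l,
            kdeg_liver = kdeg_liver, kdeg_gut = kdeg_gut,
            cv_abundance = cv_abundance, cv_kdeg = cv_kdeg,
            ph_plasma = ph_plasma, ph_iw = ph_iw, ph_bc = ph_bc)
  pos <- setdiff(names(p), c("cv_abundance", "cv_kdeg"))
  bad <- vapply(p[pos], function(x) !is.numeric(x) || length(x) != 1 ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad))
    stop("physiology values must be positive scalars: ",
         paste(pos[bad], collapse = ", "))
  for (cv in c("cv_abundance", "cv_kdeg"))
    if (p[[cv]] < 0 || p[[cv]] > 2)
      stop(cv, " must lie in [0, 2]")
  structure(p, class = "physiology")
}

#' @export
print.physiology <- function(x, ...) {
  cat("<physiology>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Oral dosing schedule
#'
#' @param dose_mg dose per administration, mg
#' @param n_doses number of administrations
#' @param interval_h dosing interval, h (ignored for a single dose)
#' @param start_h time of the first dose, h
#' @return an object of class `dose_schedule`
#' @examples
#' dose_schedule(20, n_doses = 7, interval_h = 24)  # 20 mg/day for 7 days
#' @export
dose_schedule <- function(dose_mg, n_doses = 1, interval_h = 24, start_h = 0) {
  stopifnot(is.numeric(dose_mg), length(dose_mg) == 1, dose_mg >= 0,
            n_doses >= 1, n_doses == round(n_doses), start_h >= 0)
  if (n_doses > 1 && interval_h <= 0)
    stop("interval_h must be positive for repeated dosing")
  structure(list(dose_mg = dose_mg, route = "oral", n_doses = as.integer(n_doses),
                 interval_h = interval_h, start_h = start_h),
            class = "dose_schedule")
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf("<dose_schedule> %g mg oral x %d, q%gh from t = %g h\n",
              x$dose_mg, x$n_doses, x$interval_h, x$start_h))
  invisible(x)
}

dose_times <- function(schedule) {
  schedule$start_h + schedule$interval_h * (seq_len(schedule$n_doses) - 1)
}
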