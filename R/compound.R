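#' Compound parameter set
#'
#' All drug-specific constants used by the pipeline: physicochemistry and
#' blood binding, absorption (Qgut model), distribution, elimination, and
#' CYP3A4 time-dependent-inactivation constants.  Unknown fields are
#' rejected.  Clearance may be supplied either as a microsomal intrinsic
#' clearance (`clint_hlm`, scaled to the whole liver by IVIVE) or directly
#' as a whole-liver unbound intrinsic clearance (`clint_liver_u`, L/h) as is
#' convenient for victim drugs parameterized from systemic clearance.
#'
#' @param name compound label
#' @param mw molecular weight, g/mol
#' @param logp octanol:water log partition coefficient
#' @param compound_type one of `"monoprotic base"`, `"monoprotic acid"`,
#'   `"neutral"`
#' @param pka acid dissociation constant (ignored for neutral compounds)
#' @param bp_ratio blood:plasma concentration ratio
#' @param fu_plasma fraction unbound in plasma, (0, 1]
#' @param papp_caco2 Caco-2 apparent permeability, 1e-6 cm/s (annotation)
#' @param peff_man human jejunal effective permeability, 1e-4 cm/s
#' @param solubility aqueous solubility, mg/mL (annotation)
#' @param fu_gut fraction unbound in the enterocyte, (0, 1]
#' @param qgut Qgut hybrid flow, L/h
#' @param vss steady-state volume of distribution, L/kg (input or predicted)
#' @param clint_hlm microsomal intrinsic clearance, uL/min/mg protein
#' @param clint_liver_u whole-liver unbound intrinsic clearance, L/h
#'   (overrides IVIVE scaling of `clint_hlm` when given)
#' @param kapp apparent inactivator concentration at half-maximal
#'   inactivation, uM (total in incubation; unbound via `fu_mic`)
#' @param kinact maximal inactivation rate constant, 1/h
#' @param fu_mic fraction unbound in the microsomal incubation, (0, 1]
#' @param fm_cyp3a4 fraction of hepatic (systemic) clearance via CYP3A4
#' @param clint_gut_u gut CYP3A4 unbound intrinsic clearance, L/h
#' @param ka first-order absorption rate constant, 1/h; derived from
#'   `peff_man` via [ka_from_peff()] when absent
#' @param dose_mg default oral dose, mg
#' @return an object of class `compound_params`
#' @seealso [piperine_params()], [read_compound_params()]
#' @export
compound_params <- function(name, mw, logp = NA_real_,
                            compound_type = "monoprotic base",
                            pka = NA_real_, bp_ratio, fu_plasma,
                            papp_caco2 = NA_real_, peff_man = NA_real_,
                            solubility = NA_real_, fu_gut = 1,
                            qgut = 15.7, vss, clint_hlm = NA_real_,
                            clint_liver_u = NA_real_,
                            kapp = 0, kinact = 0, fu_mic = 1,
                            fm_cyp3a4 = 0, clint_gut_u = 0, ka = NA_real_,
                            dose_mg = NA_real_) {
  x <- list(name = name, mw = mw, logp = logp, compound_type = compound_type,
            pka = pka, bp_ratio = bp_ratio, fu_plasma = fu_plasma,
            papp_caco2 = papp_caco2, peff_man = peff_man,
            solubility = solubility, fu_gut = fu_gut, qgut = qgut, vss = vss,
            clint_hlm = clint_hlm, clint_liver_u = clint_liver_u,
            kapp = kapp, kinact = kinact, fu_mic = fu_mic,
            fm_cyp3a4 = fm_cyp3a4, clint_gut_u = clint_gut_u, ka = ka,
            dose_mg = dose_mg)
  validate_compound(x)
  structure(x, class = "compound_params")
}

validate_compound <- function(x) {
  chk_frac <- function(f) {
    v <- x[[f]]
    if (!is.na(v) && (v <= 0 || v > 1))
      stop(f, " must lie in (0, 1], got ", v)
  }
  for (f in c("fu_plasma", "fu_gut", "fu_mic")) chk_frac(f)
  if (x$fm_cyp3a4 < 0 || x$fm_cyp3a4 > 1)
    stop("fm_cyp3a4 must lie in [0, 1]")
  if (x$bp_ratio <= 0) stop("bp_ratio must be positive")
  if (x$mw <= 0) stop("mw must be positive")
  if (x$kinact > 0 && x$kapp <= 0)
    stop("kapp must be positive when kinact > 0")
  for (f in c("qgut", "clint_gut_u", "kinact", "kapp"))
    if (!is.na(x[[f]]) && x[[f]] < 0) stop(f, " must be non-negative")
  if (!x$compound_type %in% c("monoprotic base", "monoprotic acid", "neutral"))
    stop("unsupported compound_type: ", x$compound_type)
  invisible(x)
}

#' @export
print.compound_params <- function(x, ...) {
  cat(sprintf("<compound_params> %s (MW %.2f, %s)\n", x$name, x$mw,
              x$compound_type))
  num <- names(x)[vapply(x, is.numeric, logical(1))]
  for (nm in setdiff(num, "mw"))
    if (!is.na(x[[nm]])) cat(sprintf("  %-14s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Piperine parameter set
#'
#' The optimized piperine model inputs: MW 285.34 g/mol, logP 1.86,
#' monoprotic base with pKa 12.22 (effectively fully ionized at
#' physiological pH), B/P 0.63, fu_plasma 0.03, Peff 5.13e-4 cm/s,
#' fu_gut 0.0211, Qgut 15.4 L/h, Vss 0.826 L/kg, pooled HLM CLint
#' 24.2 uL/min/mg, and CYP3A4 inactivation constants Kapp 6.74 uM,
#' kinact 0.558 1/h with fu_mic 0.863.
#'
#' @return a `compound_params` object
#' @export
piperine_params <- function() {
  read_compound_params(system.file("extdata", "piperine.yaml",
                                   package = "piperpbpk"))
}

#' Read / write compound parameter files
#'
#' Compound files are flat YAML with exactly the [compound_params()] field
#' names; unknown keys raise an error listing the accepted keys.
#'
#' @param path file path
#' @return `read_compound_params()` returns a `compound_params` object;
#'   `write_compound_params()` returns `path` invisibly.
#' @export
read_compound_params <- function(path) {
  if (!file.exists(path)) stop("no such compound file: ", path)
  raw <- yaml::read_yaml(path)
  accepted <- names(formals(compound_params))
  unknown <- setdiff(names(raw), accepted)
  if (length(unknown))
    stop("unknown compound parameter key(s): ",
         paste(unknown, collapse = ", "),
         "\naccepted keys: ", paste(accepted, collapse = ", "))
  do.call(compound_params, raw)
}

#' @param compound a `compound_params` object
#' @rdname read_compound_params
#' @export
write_compound_params <- function(compound, path) {
  stopifnot(inherits(compound, "compound_params"))
  x <- compound[!vapply(compound, function(v) is.numeric(v) && is.na(v),
                        logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Fraction ionized at a given pH (Henderson-Hasselbalch)
#'
#' @param pka acid dissociation constant
#' @param ph ambient pH
#' @param compound_type `"monoprotic base"`, `"monoprotic acid"` or
#'   `"neutral"`
#' @return fraction of molecules in the ionized form, in \[0, 1)
#' @examples
#' fraction_ionized(12.22, 7.4, "monoprotic base")  # ~0.999985
#' @export
fraction_ionized <- function(pka, ph, compound_type = "monoprotic base") {
  switch(compound_type,
         "monoprotic base" = 1 / (1 + 10^(ph - pka)),
         "monoprotic acid" = 1 / (1 + 10^(pka - ph)),
         "neutral" = 0,
         stop("unsupported compound_type: ", compound_type))
}

#' Fraction unbound in blood
#'
#' `fu_b = fu_plasma / (B/P)`, the binding term entering the well-stirred
#' liver model.  Values above 1 (possible for compounds excluded from
#' erythrocytes with low plasma binding) are clamped to 1 with a warning.
#'
#' @param fu_plasma fraction unbound in plasma
#' @param bp_ratio blood:plasma concentration ratio
#' @return fraction unbound in whole blood
#' @export
blood_unbound_fraction <- function(fu_plasma, bp_ratio) {
  if (bp_ratio <= 0) stop("bp_ratio must be positive")
  fu_b <- fu_plasma / bp_ratio
  if (fu_b > 1) {
    warning("fu_plasma / bp_ratio exceeds 1; clamping fu_blood to 1")
    fu_b <- 1
  }
  fu_b
}

#' Blood-cell to plasma-water partition coefficient
#'
#' Back-calculated from the measured blood:plasma ratio:
#' `Kpu_BC = (B/P - (1 - Hct)) / (Hct * fu_plasma)`.  When B/P does not
#' exceed the plasma fraction there is no measurable cell partitioning and
#' 0 is returned with a warning (the acidic-phospholipid association term
#' of the partitioning model is then 0).
#'
#' @param bp_ratio blood:plasma concentration ratio
#' @param fu_plasma fraction unbound in plasma
#' @param hematocrit erythrocyte volume fraction
#' @return unbound blood-cell partition coefficient (unitless, >= 0)
#' @export
kpu_blood_cells <- function(bp_ratio, fu_plasma, hematocrit = 0.45) {
  stopifnot(fu_plasma > 0, hematocrit > 0, hematocrit < 1)
  if (bp_ratio <= 1 - hematocrit) {
    warning("B/P <= 1 - Hct: no blood-cell partitioning; returning 0")
    return(0)
  }
  (bp_ratio - (1 - hematocrit)) / (hematocrit * fu_plasma)
}

#' Absorption rate constant from effective permeability
#'
#' Cylindrical-tube mapping `ka = 2 * Peff / R` with Peff converted from
#' 1e-4 cm/s to cm/h.
#'
#' @param peff effective human jejunal permeability, 1e-4 cm/s
#' @param radius_cm intestinal radius, cm
#' @return first-order absorption rate constant, 1/h
#' @examples
#' ka_from_peff(5.13, 1.75)  # ~2.11 per hour
#' @export
ka_from_peff <- function(peff, radius_cm = 1.75) {
  if (peff <= 0 || radius_cm <= 0) stop("peff and radius_cm must be positive")
  2 * (peff * 1e-4 * 3600) / radius_cm
}

#' Qgut hybrid flow
#'
#' `Qgut = Qvilli * CLperm / (Qvilli + CLperm)`: the hybrid
#' permeability/perfusion parameter governing intestinal first-pass
#' availability.  Provided for sensitivity analyses; the piperine model
#' takes Qgut as an input.
#'
#' @param clperm permeability clearance across the enterocyte, L/h
#' @param qvilli villous blood flow, L/h
#' @return hybrid flow, L/h; never exceeds either argument
#' @export
qgut_hybrid <- function(clperm, qvilli = 18) {
  if (qvilli <= 0) stop("qvilli must be positive")
  if (clperm < 0) stop("clperm must be non-negative")
  qvilli * clperm / (qvilli + clperm)
}
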