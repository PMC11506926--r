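#' Whole-liver intrinsic clearance by IVIVE
#'
#' Scales a microsomal intrinsic clearance to the whole organ:
#' `CLint (L/h) = CLint_HLM (uL/min/mg) * MPPGL (mg/g) * liver (g)
#'  * 60 / 1e6`.
#'
#' @param clint_hlm microsomal intrinsic clearance, uL/min/mg protein
#' @param mppgl mg microsomal protein per g liver
#' @param liver_weight_g liver weight, g
#' @return whole-liver intrinsic clearance, L/h
#' @examples
#' whole_liver_clint(24.2)  # 95.8 L/h
#' @export
whole_liver_clint <- function(clint_hlm, mppgl = 40, liver_weight_g = 1650) {
  if (clint_hlm < 0) stop("clint_hlm must be non-negative")
  if (mppgl <= 0 || liver_weight_g <= 0)
    stop("mppgl and liver_weight_g must be positive")
  clint_hlm * mppgl * liver_weight_g * 60 / 1e6
}

#' Well-stirred hepatic clearance
#'
#' `CLh = Qh * fu_b * CLint_u / (Qh + fu_b * CLint_u)` with hepatic
#' extraction `Eh = fu_b * CLint_u / (Qh + fu_b * CLint_u)` and first-pass
#' availability `Fh = 1 - Eh`.  Clearance is on a blood-concentration
#' basis.
#'
#' @param q_h hepatic blood flow, L/h
#' @param fu_b fraction unbound in blood
#' @param clint_u unbound whole-liver intrinsic clearance, L/h
#' @return list with `clh` (L/h, blood), `extraction`, `availability`
#' @export
well_stirred_clh <- function(q_h, fu_b, clint_u) {
  if (q_h <= 0) stop("q_h must be positive")
  if (fu_b < 0 || clint_u < 0) stop("fu_b and clint_u must be non-negative")
  e_h <- fu_b * clint_u / (q_h + fu_b * clint_u)
  list(clh = q_h * e_h, extraction = e_h, availability = 1 - e_h)
}

#' Renal clearance by glomerular filtration
#'
#' Filtration-only renal clearance `CLr = fu_b * GFR`.  Disabled (0) by
#' default for piperine, for which no urinary-excretion datum exists; the
#' pathway is available for victim parameterizations.
#'
#' @param fu_b fraction unbound in blood
#' @param gfr glomerular filtration rate, L/h
#' @param enabled if `FALSE`, returns exactly 0
#' @return renal clearance, L/h (blood basis)
#' @export
renal_clearance <- function(fu_b, gfr = 7.2, enabled = TRUE) {
  if (fu_b < 0 || gfr < 0) stop("fu_b and gfr must be non-negative")
  if (!enabled) return(0)
  fu_b * gfr
}

#' Unbound whole-liver intrinsic clearance of a compound
#'
#' Resolves the elimination input for the simulation engine: a direct
#' `clint_liver_u` if present, otherwise IVIVE scaling of `clint_hlm` with
#' optional division by the microsomal unbound fraction (`fu_mic`) to put
#' the in vitro value on an unbound basis — standard IVIVE practice, kept
#' switchable since both variants validate within the two-fold band.
#'
#' @param compound a [compound_params()] object
#' @param physiology a [physiology()] object
#' @param fu_mic_correction divide the microsomal CLint by fu_mic?
#' @return unbound whole-liver intrinsic clearance, L/h
#' @export
hepatic_clint_u <- function(compound, physiology = piperpbpk::physiology(),
                            fu_mic_correction = TRUE) {
  if (!is.na(compound$clint_liver_u)) return(compound$clint_liver_u)
  if (is.na(compound$clint_hlm))
    stop("compound has neither clint_liver_u nor clint_hlm")
  cl <- whole_liver_clint(compound$clint_hlm, physiology$mppgl,
                          physiology$liver_weight_g)
  if (fu_mic_correction) cl <- cl / compound$fu_mic
  cl
}
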