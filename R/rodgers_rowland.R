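#' Bundled human tissue-composition table
#'
#' Fractional extra/intracellular water, neutral lipid and neutral
#' phospholipid contents, acidic phospholipid concentrations (mg/g),
#' intracellular pH and fractional tissue volumes (L/kg body weight) for
#' the standard tissue set plus erythrocytes and a lumped rest-of-body
#' compartment.  Composition fractions are the published rat-derived
#' mechanistic-partitioning dataset applied to humans, the standard
#' practice in open implementations; volumes are adult reference values.
#'
#' @param path optional path to an alternative table (same columns)
#' @return a data.frame with columns `tissue`, `f_ew`, `f_iw`, `f_nl`,
#'   `f_np`, `ap`, `ph_iw`, `volume_frac`
#' @export
tissue_composition <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tissue_composition.tsv",
                        package = "piperpbpk")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("tissue", "f_ew", "f_iw", "f_nl", "f_np", "ap", "ph_iw",
            "volume_frac")
  if (!all(need %in% names(tab)))
    stop("tissue table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$f_ew + tab$f_iw > 1))
    stop("tissue water fractions exceed 1")
  tab
}

# octanol (or, for adipose, vegetable-oil) neutral-lipid affinity
membrane_affinity <- function(logp, tissue) {
  p <- ifelse(tissue == "adipose", 10^(1.115 * logp - 1.35), 10^logp)
  p
}

ion_ratio <- function(pka, ph, compound_type) {
  switch(compound_type,
         "monoprotic base" = 1 + 10^(pka - ph),
         "monoprotic acid" = 1 + 10^(ph - pka),
         "neutral" = 1,
         stop("unsupported compound_type: ", compound_type))
}

#' Acidic-phospholipid association constant from blood-cell partitioning
#'
#' For an ionizable base the association constant to acidic phospholipids,
#' `Ka_AP`, is back-calculated from the observed blood-cell partitioning:
#' the measured `Kpu_BC` (from B/P, fu and hematocrit) minus its water and
#' neutral-lipid components is attributed to the ionized drug bound to
#' erythrocyte acidic phospholipids.  Negative estimates are clamped to 0
#' with a warning.
#'
#' @param compound a [compound_params()] base with measured B/P and fu
#' @param tissues tissue-composition table containing a `blood_cells` row
#' @param physiology a [physiology()] object (hematocrit, plasma pH)
#' @return association constant Ka_AP, per (mg acidic phospholipid / g)
#' @export
ka_ap_from_blood <- function(compound, tissues = tissue_composition(),
                             physiology = piperpbpk::physiology()) {
  bc <- tissues[tissues$tissue == "blood_cells", ]
  if (nrow(bc) != 1) stop("tissue table is missing the blood_cells row")
  if (bc$ap <= 0) stop("blood-cell acidic phospholipid concentration is 0")
  if (compound$compound_type != "monoprotic base")
    stop("Ka_AP back-calculation applies to ionizable bases")
  kpu_bc <- kpu_blood_cells(compound$bp_ratio, compound$fu_plasma,
                            physiology$hematocrit)
  Y <- ion_ratio(compound$pka, physiology$ph_plasma, compound$compound_type)
  X <- ion_ratio(compound$pka, bc$ph_iw, compound$compound_type)
  p <- 10^compound$logp
  lipid <- (p * bc$f_nl + (0.3 * p + 0.7) * bc$f_np) / Y
  ka_ap <- (kpu_bc - bc$f_ew - (X / Y) * bc$f_iw - lipid) * Y /
    (bc$ap * 10^(compound$pka - bc$ph_iw))
  if (ka_ap < 0) {
    warning("back-calculated Ka_AP is negative; clamping to 0")
    ka_ap <- 0
  }
  ka_ap
}

#' Tissue-to-plasma-water partition coefficient (method 2)
#'
#' Mechanistic unbound partition coefficient dividing tissue water into
#' extra- and intracellular components, with ionization at the local pH,
#' association of the ionized base to acidic phospholipids (`ka_ap`), and
#' neutral lipid / neutral phospholipid partitioning from the logP-derived
#' membrane affinity:
#'
#' `Kpu = f_EW + (X/Y) f_IW + Ka_AP * AP * 10^(pKa - pH_IW) / Y +
#'        (P f_NL + (0.3 P + 0.7) f_NP) / Y`
#'
#' with `X`, `Y` the ionization ratios at intracellular and plasma pH.  For
#' acids and neutrals the acidic-phospholipid term is absent and a
#' tissue-protein association term would take its place; without measured
#' tissue albumin ratios that term is 0, so those types reduce to water +
#' lipid partitioning (the neutral-compound limit).
#'
#' @param compound a [compound_params()] object
#' @param tissue one row of the tissue-composition table
#' @param ka_ap acidic-phospholipid association constant (bases)
#' @param physiology a [physiology()] object
#' @return unbound partition coefficient (>= f_EW)
#' @export
kpu_tissue <- function(compound, tissue, ka_ap = 0,
                       physiology = piperpbpk::physiology()) {
  if (ka_ap < 0) stop("ka_ap must be non-negative")
  Y <- ion_ratio(compound$pka, physiology$ph_plasma, compound$compound_type)
  X <- ion_ratio(compound$pka, tissue$ph_iw, compound$compound_type)
  p <- membrane_affinity(compound$logp, tissue$tissue)
  lipid <- if (is.na(compound$logp)) 0 else
    (p * tissue$f_nl + (0.3 * p + 0.7) * tissue$f_np) / Y
  ap_term <- if (compound$compound_type == "monoprotic base")
    ka_ap * tissue$ap * 10^(compound$pka - tissue$ph_iw) / Y else 0
  tissue$f_ew + (X / Y) * tissue$f_iw + ap_term + lipid
}

#' Predict steady-state volume of distribution (method 2)
#'
#' Plasma-referenced mechanistic Vss:
#' `Vss = V_plasma + fu_plasma * sum_t V_t * Kpu_t`, with erythrocytes
#' included as a tissue through their fractional volume.  For ionizable
#' bases `Ka_AP` is first back-calculated from blood-cell partitioning.
#'
#' @param compound a [compound_params()] object
#' @param tissues tissue-composition table (see [tissue_composition()])
#' @param physiology a [physiology()] object
#' @param v_plasma plasma volume, L/kg body weight
#' @return a list of class `partition_result`: `kpu_by_tissue`, `ka_ap`,
#'   `vss` (L/kg)
#' @examples
#' \donttest{
#' vss_method2(piperine_params())$vss  # ~0.67 L/kg
#' }
#' @export
vss_method2 <- function(compound, tissues = tissue_composition(),
                        physiology = piperpbpk::physiology(),
                        v_plasma = 0.0424) {
  need <- c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
            "lung", "muscle", "skin", "spleen", "blood_cells")
  missing <- setdiff(need, tissues$tissue)
  if (length(missing))
    stop("tissue table is missing: ", paste(missing, collapse = ", "))
  ka_ap <- if (compound$compound_type == "monoprotic base")
    ka_ap_from_blood(compound, tissues, physiology) else 0
  kpu <- vapply(seq_len(nrow(tissues)), function(i)
    kpu_tissue(compound, tissues[i, ], ka_ap, physiology), numeric(1))
  names(kpu) <- tissues$tissue
  # erythrocyte Kpu comes from the measured B/P, not the composition model
  if (compound$compound_type == "monoprotic base")
    kpu["blood_cells"] <- kpu_blood_cells(compound$bp_ratio,
                                          compound$fu_plasma,
                                          physiology$hematocrit)
  vss <- v_plasma + compound$fu_plasma * sum(tissues$volume_frac * kpu)
  structure(list(kpu_by_tissue = kpu, ka_ap = ka_ap, vss = vss),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> Vss %.3f L/kg (Ka_AP %.3g)\n",
              x$vss, x$ka_ap))
  print(round(x$kpu_by_tissue, 2))
  invisible(x)
}
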