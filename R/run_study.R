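#' Bundled condition-level piperine CLint determinations
#'
#' The four in-house microsomal depletion conditions plus two literature
#' values, all in uL/min/mg protein; their unweighted mean is the model's
#' elimination input.
#'
#' @return data.frame with columns `clint_ul_min_mg`, `protein_mg_ml`,
#'   `substrate_uM`, `source`
#' @export
clint_table <- function() {
  utils::read.table(system.file("extdata", "piperine_clint.tsv",
                                package = "piperpbpk"),
                    header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Bundled observed piperine PK comparators
#'
#' Clinical Cmax and AUC_last for 20 mg single-dose and 20 mg/day x 7
#' multiple-dose oral piperine, used by the fold-error validation.
#'
#' @return data.frame with columns `metric`, `value`, `sd`
#' @export
observed_pk <- function() {
  utils::read.table(system.file("extdata", "observed_pk.tsv",
                                package = "piperpbpk"),
                    header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Run the full piperine FDI study
#'
#' End-to-end orchestration of the pipeline: pool the condition-level
#' CLint determinations into the elimination input, predict Vss by the
#' mechanistic method (reported alongside the input value used by the
#' simulations), simulate single-dose (20 mg) and multiple-dose
#' (20 mg/day x 7) piperine, validate against the observed clinical
#' comparators with the two-fold fold-error criterion, and co-simulate the
#' ten CYP3A4 victim drugs with and without the 7-day piperine regimen.
#'
#' @param compound piperine parameter set (default [piperine_params()])
#' @param physiology a [physiology()] object
#' @param victims list of victim `compound_params`
#'   (default [victim_fixtures()]); set to `NULL` to skip the DDI stage
#' @param observations observed-PK comparator table
#' @param single_window_h NCA window after the single dose, h
#' @param ... options forwarded to the model builders (e.g. `gut_driver`,
#'   `fu_mic_correction`)
#' @return a list of class `study_report`: `clint_pooled`, `vss_predicted`,
#'   `pk` (predicted metrics), `validation` (a [validation_report()]),
#'   `ddi` (data.frame sorted by AUC ratio), `profiles`
#' @export
run_study <- function(compound = piperine_params(),
                      physiology = piperpbpk::physiology(),
                      victims = victim_fixtures(physiology),
                      observations = observed_pk(),
                      single_window_h = 24, ...) {
  clint_pooled <- pool_clint(clint_table()$clint_ul_min_mg)
  vss_pred <- vss_method2(compound, physiology = physiology)
  single <- simulate_pk(build_model(compound, physiology,
                                    dose_schedule(compound$dose_mg), ...),
                        t_end_h = single_window_h)
  sched7 <- dose_schedule(compound$dose_mg, n_doses = 7, interval_h = 24)
  multiple <- simulate_pk(build_model(compound, physiology, sched7, ...),
                          t_end_h = 7 * 24)
  m_single <- nca(single, c(0, single_window_h))
  m_mult <- nca(multiple, c(6 * 24, 7 * 24))
  predictions <- c(single_cmax_ng_ml = m_single$cmax,
                   single_auc_ng_ml_h = m_single$auc_last,
                   multiple_cmax_ng_ml = m_mult$cmax)
  report <- validation_report(predictions, observations)
  ddi <- NULL
  if (length(victims)) {
    rows <- lapply(victims, function(v) {
      r <- cosimulate_ddi(compound, v, physiology, ...)
      data.frame(victim = r$victim, dose_mg = v$dose_mg,
                 auc_alone = r$auc_alone, auc_with = r$auc_with,
                 auc_ratio = r$auc_ratio, cmax_ratio = r$cmax_ratio,
                 flag_1_25 = r$auc_ratio >= 1.25)
    })
    ddi <- do.call(rbind, rows)
    ddi <- ddi[order(ddi$auc_ratio), ]
    rownames(ddi) <- NULL
  }
  structure(list(clint_pooled = clint_pooled, vss_predicted = vss_pred$vss,
                 vss_input = compound$vss, pk = predictions,
                 pk_multiple_auc = m_mult$auc_last,
                 validation = report, ddi = ddi,
                 profiles = list(single = as.data.frame(single),
                                 multiple = as.data.frame(multiple))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("== piperine FDI study ==\n")
  cat(sprintf("pooled CLint      %.3g uL/min/mg\n", x$clint_pooled))
  cat(sprintf("Vss predicted     %.3f L/kg (input %.3f)\n",
              x$vss_predicted, x$vss_input))
  print(x$validation)
  if (!is.null(x$ddi)) {
    cat("victim interaction (sorted by AUC ratio):\n")
    print(x$ddi[, c("victim", "dose_mg", "auc_ratio", "cmax_ratio",
                    "flag_1_25")], row.names = FALSE, digits = 3)
  }
  invisible(x)
}
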