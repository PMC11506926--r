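#' Sample a virtual population
#'
#' Between-subject variability on CYP3A4: log-normal multipliers with
#' median 1 applied to enzyme abundance (default CV 41%) and degradation
#' rate (default CV 68%) at both expression sites, using
#' `sigma = sqrt(ln(1 + CV^2))`.  Per-subject seeds are drawn from a
#' counter-based stream (`seed + subject index`), so enlarging the
#' population never reshuffles existing subjects.
#'
#' @param n_subjects number of subjects
#' @param seed master seed
#' @param physiology a [physiology()] object supplying `cv_abundance` and
#'   `cv_kdeg`
#' @return data.frame with columns `subject`, `abundance_mult`,
#'   `kdeg_mult`
#' @export
sample_population <- function(n_subjects, seed = 20241011,
                              physiology = piperpbpk::physiology()) {
  stopifnot(n_subjects >= 1)
  if (physiology$cv_abundance < 0 || physiology$cv_kdeg < 0)
    stop("population CVs must be non-negative")
  sig <- function(cv) sqrt(log(1 + cv^2))
  s_a <- sig(physiology$cv_abundance)
  s_k <- sig(physiology$cv_kdeg)
  draw <- function(i) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed((seed + i) %% .Machine$integer.max)
    stats::rnorm(2)
  }
  z <- vapply(seq_len(n_subjects), draw, numeric(2))
  data.frame(subject = seq_len(n_subjects),
             abundance_mult = exp(z[1, ] * s_a),
             kdeg_mult = exp(z[2, ] * s_k))
}

#' Run a virtual-trial design
#'
#' Executes a scenario for every subject of a trials-by-subjects design
#' (default 10 x 10 = 100 subjects) with subject-level CYP3A4 abundance
#' and turnover multipliers from [sample_population()].
#'
#' @param scenario either a [compound_params()] object (plain PK scenario;
#'   metrics from [nca()]) or a list
#'   `list(perpetrator = , victim = )` (interaction scenario; metrics from
#'   [cosimulate_ddi()])
#' @param n_trials,n_subjects trial design
#' @param seed master seed
#' @param physiology a [physiology()] object
#' @param schedule dosing schedule for the plain PK scenario
#' @param window NCA window for the plain PK scenario
#' @param ... passed to [simulate_pk()]/[cosimulate_ddi()] model builders
#' @return data.frame with one row per subject: `trial`, `subject`, the
#'   sampled multipliers, and the scenario metrics (`cmax`, `auc` or
#'   `auc_ratio`, `cmax_ratio`)
#' @export
run_trials <- function(scenario, n_trials = 10, n_subjects = 10,
                       seed = 20241011,
                       physiology = piperpbpk::physiology(),
                       schedule = NULL, window = NULL, ...) {
  pop <- sample_population(n_trials * n_subjects, seed, physiology)
  pop$trial <- rep(seq_len(n_trials), each = n_subjects)
  is_ddi <- is.list(scenario) && !inherits(scenario, "compound_params") &&
    all(c("perpetrator", "victim") %in% names(scenario))
  res <- lapply(seq_len(nrow(pop)), function(i) {
    am <- pop$abundance_mult[i]
    km <- pop$kdeg_mult[i]
    out <- try({
      if (is_ddi) {
        r <- cosimulate_ddi(scenario$perpetrator, scenario$victim,
                            physiology, abundance_mult = am,
                            kdeg_mult = km, ...)
        data.frame(auc_ratio = r$auc_ratio, cmax_ratio = r$cmax_ratio,
                   auc_with = r$auc_with, cmax_with = r$cmax_with)
      } else {
        sch <- schedule %||% dose_schedule(scenario$dose_mg)
        m <- build_model(scenario, physiology, sch, abundance_mult = am,
                         kdeg_mult = km, ...)
        prof <- simulate_pk(m)
        met <- nca(prof, window)
        data.frame(cmax = met$cmax, auc = met$auc_last, tmax = met$tmax)
      }
    }, silent = TRUE)
    if (inherits(out, "try-error"))
      stop("simulation failed for trial ", pop$trial[i], ", subject ",
           pop$subject[i], ": ", attr(out, "condition")$message)
    out
  })
  cbind(pop[, c("trial", "subject", "abundance_mult", "kdeg_mult")],
        do.call(rbind, res))
}

#' Summarize per-subject metrics
#'
#' Geometric mean (`exp(mean(log x))`), SEM on the natural scale
#' (`sd(x)/sqrt(n)`), and empirical 5th/95th percentiles — the summary
#' format used for virtual-trial exposure tables and profile bands.
#'
#' @param x positive per-subject metric values
#' @return named list: `geo_mean`, `sem`, `p5`, `p95`, `n`
#' @examples
#' summarize_metrics(c(2, 8))  # geometric mean 4
#' @export
summarize_metrics <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("metrics must be positive and finite for the geometric mean")
  list(geo_mean = exp(mean(log(x))),
       sem = stats::sd(x) / sqrt(length(x)),
       p5 = unname(stats::quantile(x, 0.05)),
       p95 = unname(stats::quantile(x, 0.95)),
       n = length(x))
}
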