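#' In vitro substrate-depletion dataset
#'
#' One microsomal depletion time course: percent of zero-time substrate
#' remaining versus incubation time at a single protein concentration.
#' Replicate incubations are averaged per time point before fitting, so a
#' dataset holds condition-level means.
#'
#' @param times sampling times, minutes; non-negative, strictly increasing,
#'   first element 0
#' @param remaining percent of zero-time substrate remaining; first element
#'   100, all values positive (required for the log transform)
#' @param protein_conc microsomal protein concentration, mg/mL
#' @param substrate_conc substrate concentration, uM (annotation)
#' @param replicate_id label
#' @return an object of class `depletion_dataset`
#' @export
depletion_dataset <- function(times, remaining, protein_conc,
                              substrate_conc = NA_real_, replicate_id = "1") {
  if (length(times) != length(remaining))
    stop("times and remaining must have equal length")
  if (length(times) < 3)
    stop("at least 3 time points are required")
  if (times[1] != 0) stop("first sampling time must be 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(remaining <= 0))
    stop("remaining percentages must be positive (log transform)")
  if (abs(remaining[1] - 100) > 1e-9)
    stop("remaining at time 0 must be 100%")
  if (protein_conc <= 0) stop("protein_conc must be positive")
  structure(list(times = times, remaining = remaining,
                 protein_conc = protein_conc,
                 substrate_conc = substrate_conc,
                 replicate_id = replicate_id),
            class = "depletion_dataset")
}

#' @export
print.depletion_dataset <- function(x, ...) {
  cat(sprintf("<depletion_dataset> %d points, HLM %g mg/mL, substrate %g uM\n",
              length(x$times), x$protein_conc, x$substrate_conc))
  print(data.frame(time_min = x$times, remaining_pct = x$remaining))
  invisible(x)
}

#' Read a delimited depletion table
#'
#' Expected format: comment/metadata header lines
#' `# protein_conc_mg_ml: <x>` and `# substrate_uM: <x>`, then a delimited
#' table with columns `time_min`, `remaining_pct` and optionally
#' `replicate`.  Replicates are averaged per time point.
#'
#' @param path file path
#' @param sep field separator (default tab)
#' @return a `depletion_dataset`
#' @export
read_depletion <- function(path, sep = "\t") {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0(key, ":"), meta, value = TRUE)
    if (!length(m)) stop("missing metadata header '# ", key, ": <value>'")
    as.numeric(sub(".*:", "", m[1]))
  }
  p <- get_meta("protein_conc_mg_ml")
  s <- tryCatch(get_meta("substrate_uM"), error = function(e) NA_real_)
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = sep)
  if (!all(c("time_min", "remaining_pct") %in% names(tab)))
    stop("depletion table needs columns time_min and remaining_pct")
  agg <- stats::aggregate(remaining_pct ~ time_min, tab, mean)
  agg <- agg[order(agg$time_min), ]
  depletion_dataset(agg$time_min, agg$remaining_pct, protein_conc = p,
                    substrate_conc = s)
}

#' Intrinsic clearance from a depletion slope
#'
#' `CLint = 1000 * slope / P`, where `slope` is the (positive) first-order
#' decay rate of ln(% remaining) per minute and `P` the microsomal protein
#' concentration in mg/mL.  The result is in mL/min/g protein, numerically
#' identical to uL/min/mg protein.
#'
#' @param slope decay rate of ln(% remaining), 1/min (>= 0)
#' @param protein_conc microsomal protein concentration, mg/mL
#' @return intrinsic clearance, uL/min/mg protein
#' @examples
#' clint_from_slope(0.010956, 0.33)  # 33.2
#' @export
clint_from_slope <- function(slope, protein_conc) {
  if (any(protein_conc <= 0)) stop("protein_conc must be positive")
  if (any(slope < 0)) stop("slope must be non-negative (decay rate)")
  1000 * slope / protein_conc
}

#' Fit a substrate-depletion time course
#'
#' Ordinary least-squares regression of the natural log of the remaining
#' substrate percentage against incubation time.  The fitted coefficient is
#' negated so the reported slope is a positive decay rate; CLint follows
#' from [clint_from_slope()].
#'
#' @param dataset a [depletion_dataset()]
#' @return an object of class `clint_estimate`: list with `slope` (1/min),
#'   `clint` (uL/min/mg), `r_squared`, and the incubation condition
#' @export
fit_depletion_slope <- function(dataset) {
  stopifnot(inherits(dataset, "depletion_dataset"))
  y <- log(dataset$remaining)
  fit <- stats::lm(y ~ dataset$times)
  slope <- max(0, -unname(stats::coef(fit)[2]))
  sst <- sum((y - mean(y))^2)  # direct R2: summary.lm warns on exact fits
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope = slope,
                 clint = clint_from_slope(slope, dataset$protein_conc),
                 r_squared = r2,
                 condition = c(protein_conc = dataset$protein_conc,
                               substrate_conc = dataset$substrate_conc)),
            class = "clint_estimate")
}

#' @export
print.clint_estimate <- function(x, ...) {
  cat(sprintf(
    "<clint_estimate> CLint %.3g uL/min/mg (slope %.4g /min, R2 %.4f)\n",
    x$clint, x$slope, x$r_squared))
  invisible(x)
}

#' Pool condition-level intrinsic clearances
#'
#' Unweighted arithmetic mean across condition-level CLint estimates — the
#' combination that yields the model input value from the in-house and
#' literature determinations.
#'
#' @param estimates a list of `clint_estimate` objects, or a numeric vector
#'   of CLint values (uL/min/mg protein)
#' @return pooled CLint, uL/min/mg protein
#' @examples
#' pool_clint(c(33.2, 12.9, 34.0, 10.6, 10.3, 44.2))  # 24.2
#' @export
pool_clint <- function(estimates) {
  if (is.list(estimates))
    estimates <- vapply(estimates, function(e) {
      if (inherits(e, "clint_estimate")) e$clint else as.numeric(e)
    }, numeric(1))
  if (!length(estimates)) stop("cannot pool an empty set of estimates")
  mean(estimates)
}
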