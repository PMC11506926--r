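#' Fold-error between predicted and observed values
#'
#' `fold_error = predicted / observed`.
#'
#' @param predicted,observed positive values on the same scale
#' @return fold-error (unitless)
#' @examples
#' fold_error(382, 290)  # 1.3 to one decimal
#' @export
fold_error <- function(predicted, observed) {
  if (any(predicted <= 0) || any(observed <= 0))
    stop("predicted and observed must be positive")
  predicted / observed
}

#' Two-fold acceptance check
#'
#' A prediction is acceptable when its fold-error lies in the inclusive
#' band `[1/fold, fold]` (default the conventional two-fold range
#' \[0.5, 2.0\]).
#'
#' @param fe fold-error(s)
#' @param fold acceptance band half-width (band is `[1/fold, fold]`)
#' @return logical vector
#' @export
within_twofold <- function(fe, fold = 2) {
  if (any(fe <= 0)) stop("fold-error must be positive")
  stopifnot(fold >= 1)
  fe >= 1 / fold & fe <= fold
}

#' Fold-error validation report
#'
#' Matches predictions to observations by metric name, computes
#' fold-errors and verdicts, and flags the overall pass.  Metrics with a
#' missing observation are listed as not evaluated, never dropped.
#'
#' @param predictions named numeric vector (or list) of predicted metrics
#' @param observations data.frame with columns `metric`, `value` (an `sd`
#'   column is carried through if present), as read from the observed-PK
#'   comparator table
#' @param fold acceptance band (see [within_twofold()])
#' @return an object of class `validation_report`: data.frame of per-metric
#'   results plus attributes `pass` (all evaluated metrics in band; NA when
#'   nothing was evaluated) and `fold`
#' @export
validation_report <- function(predictions, observations, fold = 2) {
  predictions <- unlist(predictions)
  stopifnot(is.data.frame(observations),
            all(c("metric", "value") %in% names(observations)))
  rows <- lapply(names(predictions), function(nm) {
    obs <- observations$value[observations$metric == nm]
    if (!length(obs) || is.na(obs[1]))
      return(data.frame(metric = nm, predicted = predictions[[nm]],
                        observed = NA_real_, fold_error = NA_real_,
                        within_band = NA, evaluated = FALSE))
    fe <- fold_error(predictions[[nm]], obs[1])
    data.frame(metric = nm, predicted = predictions[[nm]], observed = obs[1],
               fold_error = fe, within_band = within_twofold(fe, fold),
               evaluated = TRUE)
  })
  tab <- do.call(rbind, rows)
  pass <- if (is.null(tab) || !any(tab$evaluated)) NA else
    all(tab$within_band[tab$evaluated])
  structure(tab %||% data.frame(), class = c("validation_report",
                                             "data.frame"),
            pass = pass, fold = fold)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> band [%.3g, %.3g], pass: %s\n",
              1 / attr(x, "fold"), attr(x, "fold"), attr(x, "pass")))
  df <- as.data.frame(x)
  if (nrow(df)) {
    df$fold_error <- round(df$fold_error, 1)  # display convention
    print(df, row.names = FALSE)
  }
  invisible(x)
}
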