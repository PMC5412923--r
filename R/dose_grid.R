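#' Dose grid for a single-dose trial
#'
#' The set of doses available during the trial, together with the standardised
#' values used on the horizontal axis of the dose-inefficacy curve and the
#' subset of doses administered during the rule-based escalation phase (which
#' is also the dose set of the fixed "5+5+5+5" benchmark design).
#'
#' The default grid holds eight dose levels at 10 mg intervals from 10 to
#' 80 mg. Standardised doses are the actual doses divided by 10, a mapping
#' justified by backward fitting: see [backward_fit_standardised_dose()].
#'
#' @param actual_mg Strictly increasing vector of actual doses in mg.
#' @param standardised Strictly increasing vector of standardised (unitless)
#'   doses, one per actual dose.
#' @param period1_mg Subset of `actual_mg` used in the escalation phase and in
#'   the fixed benchmark design.
#'
#' @return An object of class `dose_grid`.
#' @examples
#' g <- dose_grid()
#' g$standardised   # 1, 2, ..., 8
#' @export
dose_grid <- function(actual_mg = seq(10, 80, by = 10),
                      standardised = actual_mg / 10,
                      period1_mg = c(10, 20, 40, 80)) {
  if (length(actual_mg) != length(standardised))
    stop("actual_mg and standardised must have the same length")
  if (any(diff(actual_mg) <= 0) || any(diff(standardised) <= 0))
    stop("doses must be strictly increasing")
  if (!all(period1_mg %in% actual_mg))
    stop("period1_mg must be a subset of actual_mg")
  structure(
    list(actual_mg = as.numeric(actual_mg),
         standardised = as.numeric(standardised),
         period1_mg = as.numeric(sort(period1_mg))),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("Dose grid:", length(x$actual_mg), "levels\n")
  print(data.frame(dose_mg = x$actual_mg, standardised = x$standardised,
                   period1 = x$actual_mg %in% x$period1_mg))
  invisible(x)
}

# map actual doses (mg) to standardised doses; errors on off-grid doses
standardise_dose <- function(grid, dose_mg) {
  idx <- match(dose_mg, grid$actual_mg)
  if (anyNA(idx))
    stop("dose(s) not on the grid: ",
         paste(unique(dose_mg[is.na(idx)]), collapse = ", "))
  grid$standardised[idx]
}

#' Backward-fit a standardised dose from an anticipated inefficacy probability
#'
#' Inverts the dose-inefficacy curve at slope 1: a dose anticipated to carry
#' inefficacy probability `p` maps to the standardised value
#' `5 - logit(p)`. Plugging in the anticipated probabilities for the likely
#' dose-inefficacy scenarios shows that dividing actual doses (mg) by 10 puts
#' them on a sensible standardised scale, which is the default mapping of
#' [dose_grid()].
#'
#' @param p Anticipated probability of inefficacy, strictly inside (0, 1).
#' @return Standardised dose `5 - log(p / (1 - p))`.
#' @examples
#' backward_fit_standardised_dose(0.95)  # ~2.06, close to 20 mg / 10
#' backward_fit_standardised_dose(0.05)  # ~7.94, close to 80 mg / 10
#' @export
backward_fit_standardised_dose <- function(p) {
  if (any(p <= 0) || any(p >= 1))
    stop("p must lie strictly inside (0, 1)")
  5 - stats::qlogis(p)
}
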