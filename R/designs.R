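#' Trial history
#'
#' Ordered per-participant records of one trial realisation: participant
#' index, study period (1 = escalation/safety, 2 = adaptive, 3 = optional
#' confirmation cohort), administered dose and the binary inefficacy
#' response (`y = 1` ineffective, `y = 0` effective).
#'
#' @param participant Integer participant indices (order of entry).
#' @param period Period labels in `{1, 2, 3}`.
#' @param dose_mg Administered doses (mg).
#' @param y Binary responses.
#' @return A data frame of class `trial_history`.
#' @export
trial_history <- function(participant = integer(), period = integer(),
                          dose_mg = numeric(), y = integer()) {
  df <- data.frame(participant = as.integer(participant),
                   period = as.integer(period),
                   dose_mg = as.numeric(dose_mg),
                   y = as.integer(y))
  if (!all(df$y %in% c(0L, 1L))) stop("responses must be 0/1")
  if (!all(df$period %in% 1:3)) stop("period must be 1, 2 or 3")
  class(df) <- c("trial_history", "data.frame")
  df
}

append_history <- function(h, period, dose_mg, y) {
  n <- nrow(h)
  rbind(h, trial_history(n + seq_along(y), rep(period, length(y)),
                         rep(dose_mg, length(y)), y))
}

#' Export / import a realisation history
#'
#' Histories round-trip through CSV (`participant, period, dose_mg, y`) so a
#' realisation can be replayed through the selection criteria when
#' debugging.
#'
#' @param h A `trial_history`.
#' @param path File path.
#' @return The path (write) or a `trial_history` (read).
#' @export
write_history_csv <- function(h, path) {
  utils::write.csv(as.data.frame(h), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history_csv
#' @export
read_history_csv <- function(path) {
  df <- utils::read.csv(path)
  trial_history(df$participant, df$period, df$dose_mg, df$y)
}

#' Design specification
#'
#' Configuration of one candidate trial design. Two kinds are supported:
#' \describe{
#'   \item{fixed}{the "5+5+5+5" benchmark: `fixed_per_dose` (5) active
#'     participants at each escalation dose, no adaptation, rule-based
#'     final selection only.}
#'   \item{adaptive}{the three-period hybrid: an escalation phase dosing
#'     `period1_per_dose` (2) participants at each escalation dose, an
#'     adaptive phase allocating `adaptive_n` (10) participants in cohorts
#'     of `cohort_size` (2) to the dose whose estimated inefficacy
#'     probability is closest to the target inefficacy level (TIL), and an
#'     optional confirmation cohort of `period3_n` (2) at the model-selected
#'     dose.}
#' }
#'
#' @param kind `"adaptive"` or `"fixed"`.
#' @param til Target inefficacy level steering the adaptive allocation;
#'   candidate values in the design work were 0.05, 0.10 and 0.20. Unused by
#'   the fixed design.
#' @param cohort_size Participants per adaptive cohort (default 2).
#' @param period1_per_dose Active participants per escalation dose in the
#'   adaptive design (default 2).
#' @param adaptive_n Total adaptive-phase participants (default 10; must be
#'   a multiple of `cohort_size`).
#' @param period3_n Size of the optional confirmation cohort (default 2).
#' @param period3 Whether the confirmation cohort is dosed (default `FALSE`,
#'   matching the reported simulations whose adaptive allocation totals 18).
#' @param fixed_per_dose Active participants per dose in the fixed design
#'   (default 5).
#' @param decision_rule Next-cohort rule: `"closest"` (dose with estimated
#'   inefficacy probability closest to the TIL, ties toward the higher dose)
#'   or `"interval"` (dose maximising posterior mass within
#'   `til +- interval_halfwidth`).
#' @param interval_halfwidth Half-width for the interval rule
#'   (default 0.025).
#' @param selection Which final-dose criteria to compute: `"rule"`,
#'   `"model"` or `"both"` (fixed designs always use `"rule"`).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(kind = c("adaptive", "fixed"), til = 0.05,
                        cohort_size = 2, period1_per_dose = 2,
                        adaptive_n = 10, period3_n = 2, period3 = FALSE,
                        fixed_per_dose = 5,
                        decision_rule = c("closest", "interval"),
                        interval_halfwidth = 0.025,
                        selection = c("both", "rule", "model")) {
  kind <- match.arg(kind)
  decision_rule <- match.arg(decision_rule)
  selection <- match.arg(selection)
  if (kind == "adaptive") {
    if (til <= 0 || til >= 1) stop("til must be in (0, 1)")
    if (adaptive_n %% cohort_size != 0)
      stop("adaptive_n must be a multiple of cohort_size")
  } else {
    selection <- "rule"
  }
  structure(
    list(kind = kind, til = if (kind == "adaptive") til else NA_real_,
         cohort_size = cohort_size, period1_per_dose = period1_per_dose,
         adaptive_n = adaptive_n, period3_n = period3_n, period3 = period3,
         fixed_per_dose = fixed_per_dose, decision_rule = decision_rule,
         interval_halfwidth = interval_halfwidth, selection = selection),
    class = "design_spec"
  )
}

#' @rdname design_spec
#' @export
fixed_design <- function(fixed_per_dose = 5) {
  design_spec("fixed", fixed_per_dose = fixed_per_dose)
}

#' @rdname design_spec
#' @param ... Further arguments passed to [design_spec()].
#' @export
adaptive_design <- function(til = 0.05, ...) {
  design_spec("adaptive", til = til, ...)
}

#' @export
print.design_spec <- function(x, ...) {
  if (x$kind == "fixed") {
    cat(sprintf("Fixed benchmark design: %d active participants per escalation dose\n",
                x$fixed_per_dose))
  } else {
    cat(sprintf(
      "Adaptive design, TIL %.0f%%: %d per escalation dose + %d adaptive (cohorts of %d)%s\n",
      100 * x$til, x$period1_per_dose, x$adaptive_n, x$cohort_size,
      if (x$period3) sprintf(" + %d confirmation", x$period3_n) else ""))
    cat("  decision rule:", x$decision_rule, "\n")
  }
  invisible(x)
}

# label for result tables: "5+5+5+5" / "5% TIL" etc.
design_label <- function(design) {
  if (design$kind == "fixed")
    paste(rep(design$fixed_per_dose, 4), collapse = "+")
  else sprintf("%g%% TIL", 100 * design$til)
}

# active-participant budget implied by a design spec
design_budget <- function(design) {
  if (design$kind == "fixed") 4 * design$fixed_per_dose
  else 4 * design$period1_per_dose + design$adaptive_n +
    if (design$period3) design$period3_n else 0
}

draw_responses <- function(scenario, dose_mg, n) {
  p <- scenario$probs[as.character(dose_mg)]
  if (anyNA(p)) stop("scenario has no probability for dose ", dose_mg, " mg")
  stats::rbinom(n, 1, p)
}

#' Simulate one realisation of the fixed benchmark design
#'
#' Doses `fixed_per_dose` participants at each escalation dose (low to
#' high), draws Bernoulli inefficacy responses from the scenario's true
#' curve, and applies the rule-based final-dose criterion. Uses R's global
#' RNG stream; seed beforehand for reproducibility.
#'
#' @param scenario A [scenario()].
#' @param design A fixed [design_spec()].
#' @param grid [dose_grid()].
#' @return List with elements `history` ([trial_history()]) and `selection`
#'   (list with `rule` = selected dose or `NA`, `model` = `NA`).
#' @export
run_fixed_realisation <- function(scenario, design = fixed_design(),
                                  grid = dose_grid()) {
  if (design$kind != "fixed") stop("design must be of kind 'fixed'")
  h <- trial_history()
  for (dose in grid$period1_mg)
    h <- append_history(h, 1L, dose,
                        draw_responses(scenario, dose, design$fixed_per_dose))
  list(history = h,
       selection = list(rule = select_dose_rule_based(h), model = NA_real_))
}

#' Simulate period 1 (escalation/safety phase) of the adaptive design
#'
#' Doses `period1_per_dose` participants at each escalation dose, in fixed
#' low-to-high order; allocation is identical across realisations, only the
#' responses vary.
#'
#' @inheritParams run_fixed_realisation
#' @param design An adaptive [design_spec()].
#' @return A [trial_history()] with period-1 records.
#' @export
run_period1 <- function(scenario, design = adaptive_design(),
                        grid = dose_grid()) {
  h <- trial_history()
  for (dose in grid$period1_mg)
    h <- append_history(h, 1L, dose,
                        draw_responses(scenario, dose, design$period1_per_dose))
  h
}

#' Choose the dose for the next adaptive cohort
#'
#' The default (`"closest"`) rule picks the grid dose whose estimated
#' probability of inefficacy is closest to the TIL — "closest to, rather
#' than below", so doses in the vicinity of the target are explored. Ties
#' are broken toward the higher dose, reflecting the belief that selecting
#' too low a dose is worse than selecting too high a dose. The
#' `"interval"` alternative picks the dose maximising the posterior mass of
#' its inefficacy probability inside `til +- delta`, falling back to the
#' closest rule if every dose carries zero mass there.
#'
#' Any grid dose may be chosen: the adaptive phase is free to move to doses
#' never previously administered.
#'
#' @param post A `crm_posterior`, or (for the closest rule only) a numeric
#'   vector of per-dose estimates named by dose in mg.
#' @param til Target inefficacy level.
#' @param grid [dose_grid()].
#' @param rule `"closest"` or `"interval"`.
#' @param delta Half-width of the interval rule's probability band.
#' @return Dose in mg.
#' @export
choose_next_dose <- function(post, til, grid = dose_grid(),
                             rule = c("closest", "interval"), delta = 0.025) {
  rule <- match.arg(rule)
  if (rule == "interval" && inherits(post, "crm_posterior")) {
    p <- stats::plogis(post$spec$intercept -
                         outer(post$beta_support, grid$standardised))
    mass <- as.vector(crossprod(post$beta_weights,
                                p >= til - delta & p <= til + delta))
    if (max(mass) > 0) {
      best <- abs(mass - max(mass)) < 1e-12
      return(max(grid$actual_mg[best]))
    }
    # empty band everywhere: fall through to the closest rule
  }
  est <- if (inherits(post, "crm_posterior")) point_estimates(post) else post
  est <- est[as.character(grid$actual_mg)]
  if (anyNA(est)) stop("estimates must cover every grid dose")
  dist <- abs(est - til)
  max(grid$actual_mg[dist <= min(dist) + 1e-12])
}

#' Rule-based final-dose criterion
#'
#' Selects the lowest dose administered during periods 1 and 2 such that
#' there are no failures (ineffective responses) at that dose or at any
#' higher administered dose. Returns `NA` when no administered dose
#' qualifies (in particular whenever the highest administered dose saw a
#' failure). Period-3 records, if present, are ignored: selection is made at
#' the end of period 2.
#'
#' @param history A non-empty [trial_history()].
#' @return Selected dose (mg) or `NA`.
#' @export
select_dose_rule_based <- function(history) {
  h <- history[history$period <= 2L, ]
  if (nrow(h) == 0) stop("history has no period 1-2 records")
  doses <- sort(unique(h$dose_mg))
  fails <- vapply(doses, function(d) sum(h$y[h$dose_mg == d]), numeric(1))
  # clean_from[i]: no failures at dose i or any higher administered dose
  clean_from <- rev(cumsum(rev(fails))) == 0
  if (!any(clean_from)) return(NA_real_)
  doses[which(clean_from)[1]]
}

#' Model-based final-dose criterion
#'
#' Selects the lowest grid dose whose estimated probability of inefficacy
#' is strictly below the TIL (in contrast to the next-cohort rule, which
#' targets the dose *closest* to the TIL). Returns `NA` when no dose
#' qualifies.
#'
#' @param post A `crm_posterior`, or a numeric vector of per-dose estimates
#'   named by dose in mg.
#' @param til Target inefficacy level.
#' @param grid [dose_grid()].
#' @return Selected dose (mg) or `NA`.
#' @export
select_dose_model_based <- function(post, til, grid = dose_grid()) {
  est <- if (inherits(post, "crm_posterior")) point_estimates(post) else post
  est <- est[as.character(grid$actual_mg)]
  if (anyNA(est)) stop("estimates must cover every grid dose")
  ok <- est < til
  if (!any(ok)) return(NA_real_)
  min(grid$actual_mg[ok])
}

#' Simulate one realisation of the three-period adaptive design
#'
#' Runs the escalation phase, then allocates the adaptive-phase cohorts one
#' at a time: before each cohort the posterior is refit to all accumulated
#' responses and the next dose chosen by [choose_next_dose()]. Both
#' final-dose criteria are computed on the period 1-2 data. When the design
#' enables the confirmation cohort and the model-based criterion selects a
#' dose, `period3_n` further participants receive that dose; their responses
#' are recorded but feed into nothing (the cohort exists to enrich PK data
#' at the carried-forward dose).
#'
#' @inheritParams run_fixed_realisation
#' @param design An adaptive [design_spec()].
#' @param model [model_spec()].
#' @return List with `history`, `selection` (list `rule`/`model`, doses or
#'   `NA`) and `posterior` (the end-of-period-2 `crm_posterior`).
#' @export
run_adaptive_realisation <- function(scenario, design = adaptive_design(),
                                     model = model_spec(),
                                     grid = dose_grid()) {
  if (design$kind != "adaptive") stop("design must be of kind 'adaptive'")
  cache <- model_cache(model, grid)
  h <- run_period1(scenario, design, grid)
  for (k in seq_len(design$adaptive_n / design$cohort_size)) {
    post <- posterior_update(h, model, grid, cache = cache)
    dose <- choose_next_dose(post, design$til, grid, design$decision_rule,
                             design$interval_halfwidth)
    h <- append_history(h, 2L, dose,
                        draw_responses(scenario, dose, design$cohort_size))
  }
  post <- posterior_update(h, model, grid, cache = cache)
  sel <- list(rule = select_dose_rule_based(h),
              model = select_dose_model_based(post, design$til, grid))
  if (design$period3 && !is.na(sel$model))
    h <- append_history(h, 3L, sel$model,
                        draw_responses(scenario, sel$model, design$period3_n))
  list(history = h, selection = sel, posterior = post)
}
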