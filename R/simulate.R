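#' Simulate a design's operating characteristics under a scenario
#'
#' Generates `n_realisations` independent realisations of the trial under
#' the given design and true dose-inefficacy scenario, and averages the
#' quantities of interest:
#' \itemize{
#'   \item `p_select`: probability of selecting each dose (or no dose) for
#'     the multiple-dosing stage, per selection criterion;
#'   \item `n_per_dose`: mean number of participants allocated each dose;
#'   \item `n_ineffective`: mean number of observed ineffective responses;
#'   \item `n_below_target`: mean number of participants treated at doses
#'     strictly below the scenario's target dose (`NA` when the scenario
#'     has no target).
#' }
#'
#' One master seed drives a vector of per-realisation substream seeds, so
#' results are reproducible and independent of evaluation order.
#'
#' @param design A [design_spec()].
#' @param scenario A [scenario()].
#' @param model [model_spec()] (used by adaptive designs only).
#' @param n_realisations Number of simulated trials (default 1000).
#' @param seed Master seed.
#' @param grid [dose_grid()].
#' @return An object of class `operating_characteristics`.
#' @examples
#' oc <- simulate_design(fixed_design(), scenario1(), n_realisations = 50,
#'                       seed = 1)
#' oc
#' @export
simulate_design <- function(design, scenario, model = model_spec(),
                            n_realisations = 1000, seed = 1,
                            grid = dose_grid()) {
  if (n_realisations < 1) stop("n_realisations must be at least 1")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_realisations)
  doses <- grid$actual_mg
  labels <- c("none", as.character(doses))
  criteria <- if (design$kind == "fixed") "rule" else
    switch(design$selection, both = c("rule", "model"),
           rule = "rule", model = "model")
  counts <- matrix(0, length(criteria), length(labels),
                   dimnames = list(criteria, labels))
  alloc <- stats::setNames(numeric(length(doses)), doses)
  n_ineff <- 0
  n_below <- 0
  target <- scenario$target_mg
  for (i in seq_len(n_realisations)) {
    set.seed(sub_seeds[i])
    res <- if (design$kind == "fixed")
      run_fixed_realisation(scenario, design, grid)
    else
      run_adaptive_realisation(scenario, design, model, grid)
    for (cr in criteria) {
      sel <- res$selection[[cr]]
      lab <- if (is.na(sel)) "none" else as.character(sel)
      counts[cr, lab] <- counts[cr, lab] + 1
    }
    tab <- table(factor(res$history$dose_mg, levels = doses))
    alloc <- alloc + as.numeric(tab)
    n_ineff <- n_ineff + sum(res$history$y)
    if (!is.na(target))
      n_below <- n_below + sum(res$history$dose_mg < target)
  }
  structure(
    list(design = design, scenario_name = scenario$name,
         target_mg = target, n_realisations = n_realisations, seed = seed,
         p_select = counts / n_realisations,
         n_per_dose = alloc / n_realisations,
         n_ineffective = n_ineff / n_realisations,
         n_below_target = if (is.na(target)) NA_real_
                          else n_below / n_realisations,
         grid = grid,
         metadata = list(method = "simulation",
                         design_label = design_label(design),
                         prior = model$prior,
                         prior_params = model$prior_params,
                         estimate = model$estimate,
                         decision_rule = design$decision_rule)),
    class = "operating_characteristics"
  )
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("Operating characteristics: %s under %s\n",
              x$metadata$design_label, x$scenario_name))
  cat(sprintf("  %s; target dose %s\n",
              if (x$metadata$method == "enumeration") "exact enumeration"
              else sprintf("%d realisations (seed %s)", x$n_realisations,
                           format(x$seed)),
              if (is.na(x$target_mg)) "none" else paste0(x$target_mg, " mg")))
  cat("N per dose:\n")
  print(round(x$n_per_dose, 2))
  cat("P(selection):\n")
  print(round(x$p_select, 2))
  cat(sprintf("N ineffective: %.2f   N below target: %s\n",
              x$n_ineffective,
              if (is.na(x$n_below_target)) "n/a"
              else sprintf("%.2f", x$n_below_target)))
  invisible(x)
}

#' Exact operating characteristics of the fixed design by enumeration
#'
#' The rule-based criterion depends on the responses only through the
#' indicator "zero failures at dose d", which for `n` independent
#' participants at a dose with true inefficacy probability `p` occurs with
#' probability `(1 - p)^n`. Enumerating the joint zero-failure indicators
#' over the four administered doses (16 events) therefore yields the exact
#' selection distribution; allocation is deterministic and the expected
#' ineffective count follows by linearity.
#'
#' This is an independent check of the stochastic engine, not a replacement
#' for it.
#'
#' @param scenario A [scenario()].
#' @param design A fixed [design_spec()].
#' @param grid [dose_grid()].
#' @return An `operating_characteristics` object with exact values
#'   (`metadata$method = "enumeration"`).
#' @export
fixed_design_oracle <- function(scenario, design = fixed_design(),
                                grid = dose_grid()) {
  if (design$kind != "fixed") stop("design must be of kind 'fixed'")
  doses <- grid$period1_mg
  n <- design$fixed_per_dose
  p <- scenario$probs[as.character(doses)]
  q_clean <- (1 - p)^n  # P(zero failures at dose)
  k <- length(doses)
  labels <- c("none", as.character(grid$actual_mg))
  p_sel <- matrix(0, 1, length(labels), dimnames = list("rule", labels))
  for (ev in 0:(2^k - 1)) {
    clean <- as.logical(bitwAnd(ev, 2^(seq_len(k) - 1)))
    pr <- prod(ifelse(clean, q_clean, 1 - q_clean))
    clean_from <- rev(cumprod(rev(clean))) == 1
    lab <- if (any(clean_from)) as.character(doses[which(clean_from)[1]])
           else "none"
    p_sel[1, lab] <- p_sel[1, lab] + pr
  }
  alloc <- stats::setNames(numeric(length(grid$actual_mg)), grid$actual_mg)
  alloc[as.character(doses)] <- n
  target <- scenario$target_mg
  structure(
    list(design = design, scenario_name = scenario$name, target_mg = target,
         n_realisations = NA_integer_, seed = NA_integer_,
         p_select = p_sel, n_per_dose = alloc,
         n_ineffective = n * sum(p),
         n_below_target = if (is.na(target)) NA_real_
                          else n * sum(doses < target),
         grid = grid,
         metadata = list(method = "enumeration",
                         design_label = design_label(design))),
    class = "operating_characteristics"
  )
}

#' Monte-Carlo stability of the summary measures across repeated runs
#'
#' Repeats the full simulation with different master seeds and reports, for
#' each summary measure, the spread (max minus min) across runs — the check
#' used to argue that 1000 realisations give acceptably stable design
#' comparisons.
#'
#' @param design,scenario,model,grid As in [simulate_design()].
#' @param n_realisations Realisations per run.
#' @param seeds Vector of at least two master seeds (one per run).
#' @param criterion Selection criterion to summarise (`"rule"` or
#'   `"model"`).
#' @return List with `per_run` (summary-measure table, one row per run) and
#'   `range` (named vector of max - min per measure).
#' @export
repeat_stability <- function(design, scenario, model = model_spec(),
                             n_realisations = 1000,
                             seeds = 1:5, criterion = "rule",
                             grid = dose_grid()) {
  if (length(seeds) < 2) stop("need at least two seeds")
  runs <- lapply(seeds, function(s) {
    oc <- simulate_design(design, scenario, model, n_realisations, s, grid)
    sm <- summary_measures(oc, scenario, criterion)
    c(sm1 = sm$sm1, sm2 = sm$sm2, sm3 = sm$sm3, sm4 = sm$sm4, wsm = sm$wsm)
  })
  per_run <- do.call(rbind, runs)
  rownames(per_run) <- paste0("seed_", seeds)
  list(per_run = per_run,
       range = apply(per_run, 2, function(v) max(v) - min(v)))
}

#' Serialise operating characteristics to JSON
#'
#' Full-precision values plus embedded run metadata (design, scenario,
#' seed, prior, decision rule).
#'
#' @param oc An `operating_characteristics` object.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @export
oc_to_json <- function(oc, path = NULL) {
  obj <- list(
    design = oc$metadata$design_label, scenario = oc$scenario_name,
    target_mg = oc$target_mg, n_realisations = oc$n_realisations,
    seed = oc$seed,
    p_select = apply(oc$p_select, 1, as.list, simplify = FALSE),
    n_per_dose = as.list(oc$n_per_dose),
    n_ineffective = oc$n_ineffective,
    n_below_target = oc$n_below_target,
    metadata = oc$metadata)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
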