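#' Experiment configuration
#'
#' Bundles everything needed to reproduce a design-comparison experiment:
#' the candidate designs, the scenario bank, the model specification, the
#' number of realisations and the master seed. The default configuration is
#' the final comparison set: the fixed benchmark plus adaptive designs at
#' 5%, 10% and 20% TIL, over the seven-scenario bank, 1000 realisations
#' each.
#'
#' @param designs Named list of [design_spec()] objects; the first `fixed`
#'   design is used as the benchmark for difference tables.
#' @param scenarios Named list of [scenario()] objects.
#' @param model [model_spec()].
#' @param n_realisations Realisations per (design, scenario) cell.
#' @param seed Master seed; every cell receives its own substream seed.
#' @param grid [dose_grid()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(designs = list(`5+5+5+5` = fixed_design(),
                                      `5% TIL` = adaptive_design(0.05),
                                      `10% TIL` = adaptive_design(0.10),
                                      `20% TIL` = adaptive_design(0.20)),
                       scenarios = scenario_bank(),
                       model = model_spec(),
                       n_realisations = 1000, seed = 1,
                       grid = dose_grid()) {
  structure(list(designs = designs, scenarios = scenarios, model = model,
                 n_realisations = n_realisations, seed = seed, grid = grid),
            class = "run_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Recognised top-level keys (all optional): `n_realisations`, `seed`,
#' `tils` (vector of adaptive TILs), `include_fixed` (default `TRUE`),
#' `decision_rule`, `prior` and `prior_params`, `estimate`, `period3`,
#' `scenarios` (names from the bank, e.g. `["scenario1", "scenario4"]`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  tils <- cfg$tils %||% c(0.05, 0.10, 0.20)
  rule <- cfg$decision_rule %||% "closest"
  period3 <- cfg$period3 %||% FALSE
  designs <- list()
  if (cfg$include_fixed %||% TRUE) designs[["5+5+5+5"]] <- fixed_design()
  for (til in tils)
    designs[[sprintf("%g%% TIL", 100 * til)]] <-
      adaptive_design(til, decision_rule = rule, period3 = period3)
  bank <- scenario_bank()
  scenarios <- if (is.null(cfg$scenarios)) bank else bank[unlist(cfg$scenarios)]
  if (anyNA(names(scenarios))) stop("unknown scenario name in config")
  model <- model_spec(prior = cfg$prior %||% "uniform",
                      prior_params = cfg$prior_params,
                      estimate = cfg$estimate %||% "median")
  run_config(designs, scenarios, model,
             n_realisations = cfg$n_realisations %||% 1000,
             seed = cfg$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full design-comparison experiment
#'
#' Simulates every (design, scenario) cell of the configuration, then
#' derives summary measures and benchmark differences. A cell that errors
#' is recorded (with its message) and the run continues. When `out_dir` is
#' given, per-scenario operating-characteristic tables, the summary-measure
#' table and the difference table are written as CSV along with a JSON
#' result bundle.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param verbose Print per-cell progress messages.
#' @return An object of class `crm_experiment`: list with `results` (cell
#'   list of `operating_characteristics`), `summary` (data frame of summary
#'   measures per cell and criterion), `differences` (data frame of
#'   adaptive-minus-benchmark differences) and `config`.
#' @export
run_experiment <- function(config = run_config(), out_dir = NULL,
                           verbose = FALSE) {
  set.seed(config$seed)
  cells <- expand.grid(design = names(config$designs),
                       scenario = names(config$scenarios),
                       stringsAsFactors = FALSE)
  cell_seeds <- sample.int(.Machine$integer.max, nrow(cells))
  results <- list()
  for (r in seq_len(nrow(cells))) {
    dn <- cells$design[r]; sn <- cells$scenario[r]
    key <- paste(dn, sn, sep = " | ")
    if (verbose) message("simulating ", key)
    results[[key]] <- tryCatch(
      simulate_design(config$designs[[dn]], config$scenarios[[sn]],
                      config$model, config$n_realisations,
                      seed = cell_seeds[r], grid = config$grid),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "cell_error"))
  }
  summary_df <- experiment_summary(results, cells, config)
  diff_df <- experiment_differences(summary_df, config)
  exp <- structure(list(results = results, cells = cells,
                        summary = summary_df, differences = diff_df,
                        config = config),
                   class = "crm_experiment")
  if (!is.null(out_dir)) render_tables(exp, out_dir)
  exp
}

criteria_of <- function(design) {
  if (design$kind == "fixed") "rule"
  else switch(design$selection, both = c("rule", "model"),
              rule = "rule", model = "model")
}

experiment_summary <- function(results, cells, config) {
  rows <- list()
  for (r in seq_len(nrow(cells))) {
    dn <- cells$design[r]; sn <- cells$scenario[r]
    oc <- results[[paste(dn, sn, sep = " | ")]]
    if (inherits(oc, "cell_error")) next
    for (cr in criteria_of(config$designs[[dn]])) {
      sm <- summary_measures(oc, config$scenarios[[sn]], cr)
      rows[[length(rows) + 1]] <- data.frame(
        design = dn, scenario = sn, criterion = cr,
        sm1 = sm$sm1, sm2 = sm$sm2, sm3 = sm$sm3, sm4 = sm$sm4,
        wsm = sm$wsm)
    }
  }
  do.call(rbind, rows)
}

experiment_differences <- function(summary_df, config) {
  bench_name <- names(config$designs)[vapply(config$designs,
                                             function(d) d$kind == "fixed",
                                             logical(1))][1]
  if (is.na(bench_name) || is.null(summary_df)) return(NULL)
  bench <- summary_df[summary_df$design == bench_name &
                        summary_df$criterion == "rule", ]
  rows <- list()
  adapt <- summary_df[summary_df$design != bench_name, ]
  for (r in seq_len(nrow(adapt))) {
    b <- bench[bench$scenario == adapt$scenario[r], ]
    if (nrow(b) != 1) next
    rows[[length(rows) + 1]] <- data.frame(
      design = adapt$design[r], scenario = adapt$scenario[r],
      criterion = adapt$criterion[r],
      sm1 = adapt$sm1[r] - b$sm1, sm2 = adapt$sm2[r] - b$sm2,
      sm3 = adapt$sm3[r] - b$sm3, sm4 = adapt$sm4[r] - b$sm4,
      wsm = adapt$wsm[r] - b$wsm)
  }
  do.call(rbind, rows)
}

#' @export
print.crm_experiment <- function(x, ...) {
  cat(sprintf("Design-comparison experiment: %d designs x %d scenarios, %d realisations each\n",
              length(x$config$designs), length(x$config$scenarios),
              x$config$n_realisations))
  failed <- vapply(x$results, inherits, logical(1), "cell_error")
  if (any(failed)) cat("Failed cells:", paste(names(x$results)[failed],
                                              collapse = ", "), "\n")
  cat("Summary measures:\n")
  print(cbind(x$summary[, 1:3], round(x$summary[, -(1:3)], 2)),
        row.names = FALSE)
  invisible(x)
}

#' Operating-characteristic table for one scenario
#'
#' Lays out the per-design operating characteristics in the standard
#' reporting shape: for each design a block of rows — mean participants per
#' dose, then selection probabilities per criterion — with trailing columns
#' for the mean ineffective count and the mean count dosed below target.
#' Values are rounded to two decimals for display.
#'
#' @param exp A `crm_experiment` from [run_experiment()].
#' @param scenario_name Name of a scenario in the experiment.
#' @return A data frame.
#' @export
oc_table <- function(exp, scenario_name) {
  if (!scenario_name %in% names(exp$config$scenarios))
    stop("scenario '", scenario_name, "' not in this experiment")
  grid <- exp$config$grid
  dose_cols <- as.character(grid$actual_mg)
  rows <- list()
  for (dn in names(exp$config$designs)) {
    oc <- exp$results[[paste(dn, scenario_name, sep = " | ")]]
    if (inherits(oc, "cell_error")) stop("missing result for design ", dn,
                                         ": ", oc$message)
    base <- stats::setNames(rep(NA_real_, 1 + length(dose_cols) + 2),
                            c("none", dose_cols, "n_ineffective",
                              "n_below_target"))
    alloc <- base
    alloc[dose_cols] <- round(oc$n_per_dose[dose_cols], 2)
    alloc["n_ineffective"] <- round(oc$n_ineffective, 2)
    alloc["n_below_target"] <- round(oc$n_below_target, 2)
    rows[[paste(dn, "N per dose")]] <- alloc
    for (cr in rownames(oc$p_select)) {
      sel <- base
      sel[c("none", dose_cols)] <- round(oc$p_select[cr,
                                                     c("none", dose_cols)], 2)
      rows[[paste0(dn, " P(selection) - ", cr)]] <- sel
    }
  }
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  cbind(row_label = rownames(out), out, row.names = NULL)
}

#' Write experiment tables to CSV
#'
#' One operating-characteristic table per scenario
#' (`oc_<scenario>.csv`), the summary-measure table
#' (`summary_measures.csv`), the benchmark-difference table
#' (`design_differences.csv`) and a JSON bundle of all cell results with
#' run metadata (`results.json`).
#'
#' @param exp A `crm_experiment`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
render_tables <- function(exp, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (sn in names(exp$config$scenarios)) {
    f <- file.path(out_dir, paste0("oc_", sn, ".csv"))
    utils::write.csv(oc_table(exp, sn), f, row.names = FALSE, na = "")
    files <- c(files, f)
  }
  f <- file.path(out_dir, "summary_measures.csv")
  utils::write.csv(exp$summary, f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(exp$differences)) {
    f <- file.path(out_dir, "design_differences.csv")
    utils::write.csv(exp$differences, f, row.names = FALSE)
    files <- c(files, f)
  }
  ok <- !vapply(exp$results, inherits, logical(1), "cell_error")
  bundle <- lapply(exp$results[ok], function(oc)
    jsonlite::parse_json(oc_to_json(oc)))
  f <- file.path(out_dir, "results.json")
  jsonlite::write_json(
    list(seed = exp$config$seed, n_realisations = exp$config$n_realisations,
         cells = bundle),
    f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}

#' Benchmark-difference and allocation plots
#'
#' `plot_design_differences` draws, per scenario and summary measure, the
#' adaptive-minus-benchmark difference (positive = adaptive better), with
#' colour for the TIL and shape for the selection criterion.
#' `plot_target_allocation` draws stacked mean participant counts at the
#' target dose and above, per design, for scenarios with a target.
#' `render_plots` writes both to files.
#'
#' @param exp A `crm_experiment`.
#' @return A ggplot object.
#' @export
plot_design_differences <- function(exp) {
  df <- exp$differences
  if (is.null(df)) stop("experiment has no benchmark differences")
  long <- do.call(rbind, lapply(c("sm1", "sm2", "sm3", "sm4", "wsm"),
    function(m) data.frame(df[, c("design", "scenario", "criterion")],
                           measure = toupper(m), difference = df[[m]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$measure, y = .data$difference,
                                     colour = .data$design,
                                     shape = .data$criterion)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        size = 2) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(y = "difference vs benchmark (positive = adaptive better)",
                  x = NULL) +
    ggplot2::theme_bw()
}

#' @rdname plot_design_differences
#' @export
plot_target_allocation <- function(exp) {
  rows <- list()
  for (sn in names(exp$config$scenarios)) {
    sc <- exp$config$scenarios[[sn]]
    if (is.na(sc$target_mg)) next
    for (dn in names(exp$config$designs)) {
      oc <- exp$results[[paste(dn, sn, sep = " | ")]]
      if (inherits(oc, "cell_error")) next
      doses <- as.numeric(names(oc$n_per_dose))
      keep <- doses >= sc$target_mg
      rows[[length(rows) + 1]] <- data.frame(
        scenario = sn, design = dn, dose_mg = doses[keep],
        n = as.numeric(oc$n_per_dose[keep]))
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) stop("no scenarios with a target dose in this experiment")
  df$dose_mg <- stats::reorder(factor(df$dose_mg), -df$dose_mg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$design, y = .data$n,
                                   fill = .data$dose_mg)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(y = "mean participants at target dose and above",
                  x = NULL, fill = "dose (mg)") +
    ggplot2::theme_bw()
}

#' @rdname plot_design_differences
#' @param out_dir Output directory.
#' @param device Plot file format (default `"pdf"`, headless safe).
#' @export
render_plots <- function(exp, out_dir, device = "pdf") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  if (!is.null(exp$differences)) {
    f <- file.path(out_dir, paste0("design_differences.", device))
    ggplot2::ggsave(f, plot_design_differences(exp), width = 9, height = 6)
    files <- c(files, f)
  }
  has_target <- any(!vapply(exp$config$scenarios,
                            function(s) is.na(s$target_mg), logical(1)))
  if (has_target) {
    f <- file.path(out_dir, paste0("target_allocation.", device))
    ggplot2::ggsave(f, plot_target_allocation(exp), width = 9, height = 6)
    files <- c(files, f)
  }
  invisible(files)
}

#' Sensitivity of the adaptive design to prior and decision rule
#'
#' The reported adaptive-design performance depends on two configuration
#' choices the published account leaves open: the diffuse prior on the
#' slope and the exact next-cohort decision rule. This helper simulates the
#' adaptive design under the 2 x 2 grid (uniform vs exponential prior,
#' closest-to-TIL vs interval rule) and tabulates the rule-based and
#' model-based probabilities of selecting the scenario's target dose.
#'
#' @param scenario A [scenario()].
#' @param til Target inefficacy level (default 0.05).
#' @param n_realisations Realisations per configuration.
#' @param seed Master seed (each configuration uses the same seed, so
#'   differences are attributable to the configuration).
#' @param grid [dose_grid()].
#' @return Data frame with one row per configuration.
#' @export
til_sensitivity <- function(scenario, til = 0.05, n_realisations = 200,
                            seed = 1, grid = dose_grid()) {
  if (is.na(scenario$target_mg))
    stop("sensitivity table needs a scenario with a target dose")
  tgt <- as.character(scenario$target_mg)
  rows <- list()
  for (prior in c("uniform", "exponential")) {
    for (rule in c("closest", "interval")) {
      oc <- simulate_design(adaptive_design(til, decision_rule = rule),
                            scenario, model_spec(prior = prior),
                            n_realisations, seed, grid)
      rows[[length(rows) + 1]] <- data.frame(
        prior = prior, decision_rule = rule,
        p_select_target_rule = unname(oc$p_select["rule", tgt]),
        p_select_target_model = unname(oc$p_select["model", tgt]))
    }
  }
  do.call(rbind, rows)
}
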