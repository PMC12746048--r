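# End-to-end study orchestration: suite -> gamma metrics -> ROC -> tables.

#' Study configuration
#'
#' Defaults reproduce the study design: the 7 criteria of
#' [study_criteria()] under both normalizations (14 metrics), a 20%
#' low-dose threshold, a 95% tolerance passing rate, and ROC labelings at
#' surrogate PTV mean-dose changes above 5%, 10% and 20%.
#'
#' @param criteria list of `c(dose_diff_pct, dta_mm)` pairs.
#' @param normalizations subset of `c("global", "local")`.
#' @param threshold_pct low-dose threshold, percent of the reference
#'   maximum.
#' @param pass_limit gamma pass limit.
#' @param tolerance_pct tolerance passing rate, percent.
#' @param delta_thresholds_pct deviation magnitudes (percent) defining the
#'   positive class of each ROC labeling.
#' @param suite a [suite_config()].
#' @param seed master seed.
#' @param output_dir directory for the report bundle, or `NULL` to skip
#'   writing.
#' @return a config list for [run_study()].
#' @export
study_config <- function(criteria = list(c(3, 3), c(5, 3), c(5, 5), c(7, 5),
                                         c(10, 1), c(10, 3), c(10, 5)),
                         normalizations = c("global", "local"),
                         threshold_pct = 20, pass_limit = 1,
                         tolerance_pct = 95,
                         delta_thresholds_pct = c(5, 10, 20),
                         suite = suite_config(), seed = 1L,
                         output_dir = NULL) {
  list(criteria = criteria, normalizations = normalizations,
       threshold_pct = threshold_pct, pass_limit = pass_limit,
       tolerance_pct = tolerance_pct,
       delta_thresholds_pct = delta_thresholds_pct,
       suite = suite, seed = seed, output_dir = output_dir)
}

study_criteria_list <- function(config) {
  out <- list()
  for (nm in config$normalizations)
    for (p in config$criteria)
      out[[length(out) + 1L]] <- gamma_criterion(p[1], p[2], nm,
                                                 config$threshold_pct,
                                                 config$pass_limit)
  out
}

#' Evaluate all gamma metrics over a scenario suite
#'
#' @param scenarios list of scenarios (from [generate_suite()] or
#'   [load_suite()]).
#' @param criteria list of [gamma_criterion] objects.
#' @return long-format data.frame, one row per scenario x metric:
#'   `scenario_id`, `failure_mode`, `delta_dmean_pct`, `dose_diff_pct`,
#'   `dta_mm`, `normalization`, `metric`, `passing_rate_pct`, `error`.
#' @export
evaluate_suite <- function(scenarios, criteria = study_criteria()) {
  do.call(rbind, lapply(scenarios, function(s) {
    tab <- evaluate_criteria_set(s$reference, s$evaluated, criteria)
    cbind(data.frame(scenario_id = s$scenario_id,
                     failure_mode = s$failure_mode,
                     delta_dmean_pct = s$delta_dmean_pct,
                     stringsAsFactors = FALSE),
          tab, row.names = NULL)
  }))
}

#' ROC analysis of a passing-rate table
#'
#' One ROC per gamma metric and deviation threshold, labeling a scenario
#' positive when its absolute surrogate PTV mean-dose change exceeds the
#' threshold. A labeling with a single class yields an "undefined ROC" row
#' (NA AUC, reason recorded) rather than an error.
#'
#' @param results long table from [evaluate_suite()].
#' @param delta_thresholds_pct deviation thresholds, percent.
#' @return data.frame with one row per metric: `metric`,
#'   `normalization`, `dose_diff_pct`, `dta_mm`, then per threshold `T`
#'   columns `auc_gtT`, `optimal_passing_rate_gtT`, `sens_gtT`,
#'   `spec_gtT`, `roc_note_gtT`.
#' @export
roc_table <- function(results, delta_thresholds_pct = c(5, 10, 20)) {
  metrics <- unique(results[c("metric", "normalization",
                              "dose_diff_pct", "dta_mm")])
  out <- metrics
  for (thr in delta_thresholds_pct) {
    suf <- sprintf("gt%g", thr)
    cols <- data.frame(auc = rep(NA_real_, nrow(metrics)),
                       opt = NA_real_, sens = NA_real_, spec = NA_real_,
                       note = NA_character_, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(metrics))) {
      d <- results[results$metric == metrics$metric[i] &
                   !is.na(results$passing_rate_pct), , drop = FALSE]
      label <- abs(d$delta_dmean_pct) > thr
      roc <- tryCatch(build_roc(d$passing_rate_pct, label),
                      error = function(e) e)
      if (inherits(roc, "error")) {
        cols$note[i] <- conditionMessage(roc)
      } else {
        cols$auc[i] <- roc$auc
        cols$opt[i] <- roc$optimal_cutoff_pct
        cols$sens[i] <- roc$sens_at_opt
        cols$spec[i] <- roc$spec_at_opt
      }
    }
    names(cols) <- paste0(c("auc_", "optimal_passing_rate_", "sens_",
                            "spec_", "roc_note_"), suf)
    out <- cbind(out, cols)
  }
  rownames(out) <- NULL
  out
}

#' Run the full transit-dosimetry detection study
#'
#' Generates the scenario suite, evaluates every gamma metric on every
#' scenario, performs the ROC analysis at each deviation threshold and
#' computes tolerance-failure fractions. Fully deterministic given the
#' config (which embeds the seed). When `config$output_dir` is set, the
#' bundle is written as CSV (`manifest.csv`, `passing_rates.csv`,
#' `roc_summary.csv`, `tolerance_failures.csv`) plus `run_log.txt`.
#'
#' @param config a [study_config()].
#' @return object of class `study_result`: `scenarios`, `manifest`,
#'   `results`, `roc`, `tolerance`, `config`.
#' @export
run_study <- function(config = study_config()) {
  t0 <- Sys.time()
  scenarios <- generate_suite(config$suite, config$seed)
  manifest <- suite_manifest(scenarios)
  results <- evaluate_suite(scenarios, study_criteria_list(config))
  roc <- roc_table(results, config$delta_thresholds_pct)
  tolerance <- tolerance_failure_fraction(results, config$tolerance_pct)
  out <- structure(list(scenarios = scenarios, manifest = manifest,
                        results = results, roc = roc, tolerance = tolerance,
                        config = config),
                   class = "study_result")
  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(results, file.path(dir, "passing_rates.csv"), row.names = FALSE)
    utils::write.csv(roc, file.path(dir, "roc_summary.csv"), row.names = FALSE)
    utils::write.csv(tolerance, file.path(dir, "tolerance_failures.csv"),
                     row.names = FALSE)
    writeLines(c(sprintf("transitgamma %s",
                         as.character(utils::packageVersion("transitgamma"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("scenarios: %d, metrics: %d", length(scenarios),
                         length(unique(results$metric))),
                 sprintf("tolerance: %g%%, thresholds: %s", config$tolerance_pct,
                         paste(config$delta_thresholds_pct, collapse = ", ")),
                 sprintf("elapsed: %.1f s",
                         as.numeric(difftime(Sys.time(), t0, units = "secs")))),
               file.path(dir, "run_log.txt"))
  }
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("transit-dosimetry study: %d scenarios x %d gamma metrics\n",
              length(x$scenarios), length(unique(x$results$metric))))
  print(report_tables(x$roc)$global)
  invisible(x)
}

#' Render the per-normalization AUC / optimal passing-rate tables
#'
#' Formats the ROC summary the way the study's result tables are
#' presented: one table per normalization, a row per criterion, and per
#' deviation threshold the AUC (2 decimals) and the optimal passing rate
#' (1 decimal).
#'
#' @param roc a data.frame from [roc_table()].
#' @return named list of data.frames, one per normalization present.
#' @export
report_tables <- function(roc) {
  sufs <- sub("^auc_", "", grep("^auc_", names(roc), value = TRUE))
  out <- list()
  for (nm in unique(roc$normalization)) {
    rows <- roc[roc$normalization == nm, , drop = FALSE]
    tab <- data.frame(criterion = sprintf("%g%%/%gmm", rows$dose_diff_pct,
                                          rows$dta_mm))
    for (s in sufs) {
      tab[[paste0("auc_", s)]] <- sprintf("%.2f", rows[[paste0("auc_", s)]])
      tab[[paste0("optimal_passing_rate_", s)]] <-
        sprintf("%.1f", rows[[paste0("optimal_passing_rate_", s)]])
    }
    rownames(tab) <- NULL
    out[[nm]] <- tab
  }
  out
}
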