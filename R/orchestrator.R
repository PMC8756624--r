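#' Experiment configuration
#'
#' Collects every knob of the end-to-end benchmark: cohort generation,
#' the scenario grid, the method list, imputer tuning settings, the
#' evaluation threshold, and the replicate count. Defaults are the
#' canonical study conditions: the published count profile in exact mode
#' (n = 1468), the 3-mechanism x 6-proportion grid, all eight methods,
#' full grids with 10-fold CV, threshold 0.5, one replicate.
#'
#' @param cohort_mode `"exact"` or `"stochastic"`.
#' @param cohort_n Cohort size (stochastic mode only).
#' @param dependence Coupling list for stochastic mode
#'   (see [generate_cohort()]).
#' @param proportions,mechanisms Scenario grid.
#' @param methods Methods to run (subset of [imputation_methods()]).
#' @param threshold Evaluation cutoff.
#' @param fast Use the reduced tuning profile of [imputer_config()].
#' @param replicates Independent amputation replicates per scenario;
#'   metrics are averaged over replicates.
#' @param seed Master seed; every stage's randomness derives from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(cohort_mode = "exact", cohort_n = NULL,
                              dependence = NULL,
                              proportions = c(0.05, 0.10, 0.15, 0.20, 0.30, 0.50),
                              mechanisms = c("MCAR", "MAR_1_2", "MAR_2_1"),
                              methods = imputation_methods(),
                              threshold = 0.5, fast = FALSE,
                              replicates = 1L, seed = 1L) {
  stopifnot(cohort_mode %in% c("exact", "stochastic"),
            all(methods %in% imputation_methods()),
            all(mechanisms %in% c("MCAR", "MAR_1_2", "MAR_2_1")),
            all(proportions >= 0 & proportions <= 1),
            replicates >= 1)
  structure(list(cohort_mode = cohort_mode, cohort_n = cohort_n,
                 dependence = dependence, proportions = proportions,
                 mechanisms = mechanisms, methods = methods,
                 threshold = threshold, fast = isTRUE(fast),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' The YAML schema mirrors the arguments of [experiment_config()]; absent
#' keys take the documented defaults. `dependence` entries are lists of
#' `[a, b, strength]`.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        names(formals(experiment_config)))]
  if (!is.null(args$dependence))
    args$dependence <- lapply(args$dependence, function(cp)
      list(cp[[1]], cp[[2]], as.numeric(cp[[3]])))
  do.call(experiment_config, args)
}

#' Run the full imputation benchmark
#'
#' Executes the four-step design: generate the cohort, compute the
#' complete-data reference metrics, then for every scenario ampute the
#' target variable, impute with every configured method, and evaluate the
#' downstream discharge model; finally aggregate the Average rows and run
#' the EL-versus-others significance tests. Fully deterministic given
#' `config$seed`. A failure in one scenario-method cell is recorded in the
#' results (`error` column) and the run continues.
#'
#' @param config An [experiment_config()].
#' @param verbose Print per-stage progress and timings.
#' @return A `report_bundle`: `results` (long data frame), `averages`,
#'   `stats` (EL comparisons; NULL if EL absent), `reference` metrics,
#'   `cohort`, and a provenance `manifest`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  icfg <- imputer_config(fast = config$fast,
                         seed = derive_seed(config$seed, 11L))

  cohort <- generate_cohort(published_profile(), mode = config$cohort_mode,
                            n = config$cohort_n,
                            dependence = config$dependence,
                            seed = derive_seed(config$seed, 1L))
  say("cohort generated: n=%d", nrow(cohort))
  ref <- evaluate_scenario(cohort, threshold = config$threshold)$metrics
  say("reference: sens=%.3f auc=%.3f kappa=%.3f",
      ref$sensitivity, ref$auc, ref$kappa)

  rows <- list()
  for (rep_i in seq_len(config$replicates)) {
    scenarios <- enumerate_scenarios(config$proportions, config$mechanisms,
                                     seed_base = derive_seed(config$seed,
                                                             100L + rep_i))
    for (sc in scenarios) {
      ts <- Sys.time()
      inc <- ampute(cohort, sc)
      tuned <- list()
      single <- intersect(c("LR", "RF", "NN", "SVM"), config$methods)
      for (m in config$methods) {
        res <- tryCatch({
          comp <- impute_with(inc, m, icfg,
                              tuned = if (m == "EL") tuned
                                      else tuned[[m]])
          if (m %in% single && !is.null(comp$tuned) &&
              inherits(comp$tuned, "tuned_model"))
            tuned[[m]] <- comp$tuned
          ev <- evaluate_scenario(comp, threshold = config$threshold,
                                  reference = ref)
          data.frame(replicate = rep_i, mechanism = sc$mechanism,
                     proportion = sc$p, method = m,
                     sensitivity = ev$metrics$sensitivity,
                     auc = ev$metrics$auc, kappa = ev$metrics$kappa,
                     error = NA_character_, stringsAsFactors = FALSE)
        }, error = function(e)
          data.frame(replicate = rep_i, mechanism = sc$mechanism,
                     proportion = sc$p, method = m,
                     sensitivity = NA_real_, auc = NA_real_,
                     kappa = NA_real_, error = conditionMessage(e),
                     stringsAsFactors = FALSE))
        rows[[length(rows) + 1L]] <- res
      }
      say("scenario %s p=%.2f done in %.1fs", sc$mechanism, sc$p,
          as.numeric(difftime(Sys.time(), ts, units = "secs")))
    }
  }
  results <- do.call(rbind, rows)
  # average metrics over replicates per scenario-method cell
  agg <- stats::aggregate(
    results[c("sensitivity", "auc", "kappa")],
    by = results[c("mechanism", "proportion", "method")],
    FUN = mean)
  agg <- agg[order(agg$mechanism, agg$method, agg$proportion), ,
             drop = FALSE]
  rownames(agg) <- NULL

  averages <- stats::aggregate(
    agg[c("sensitivity", "auc", "kappa")],
    by = agg[c("mechanism", "method")],
    FUN = function(v) round(mean(v), 3))
  rownames(averages) <- NULL

  stats_tbl <- if ("EL" %in% config$methods && length(config$methods) > 1 &&
                   !anyNA(agg$sensitivity))
    compare_el(agg) else NULL

  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    reference = list(sensitivity = ref$sensitivity, auc = ref$auc,
                     kappa = ref$kappa),
    n_records = nrow(cohort),
    n_cells = nrow(agg),
    r_version = as.character(getRversion()),
    elapsed_secs = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  structure(list(results = agg, raw_results = results,
                 averages = averages, stats = stats_tbl,
                 reference = ref, cohort = cohort, manifest = manifest),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d result cells | reference sens=%.3f auc=%.3f kappa=%.3f\n",
              nrow(x$results), x$reference$sensitivity, x$reference$auc,
              x$reference$kappa))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes `results.csv` (long format, full precision), `averages.csv`,
#' `stats.csv` (when present), `manifest.json`, and one wide pivoted table
#' per mechanism (`wide_<mechanism>.csv`: metric x proportion rows
#' including an Average row, method columns, 3-decimal rendering).
#'
#' @param bundle A `report_bundle` from [run_experiment()].
#' @param outdir Output directory (created if absent).
#' @return Character vector of written file paths, invisibly.
#' @export
write_report <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(bundle$results, "results.csv")
  wr(bundle$averages, "averages.csv")
  if (!is.null(bundle$stats)) wr(bundle$stats, "stats.csv")
  for (mech in unique(bundle$results$mechanism)) {
    wide <- pivot_mechanism(bundle$results, mech)
    wr(wide, paste0("wide_", mech, ".csv"))
  }
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(bundle$manifest, mp, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, mp)
  invisible(paths)
}

# one mechanism's results in benchmark-table orientation:
# metric x proportion rows (plus an Average row per metric), method columns
pivot_mechanism <- function(results, mechanism) {
  sub <- results[results$mechanism == mechanism, , drop = FALSE]
  methods <- unique(sub$method)
  props <- sort(unique(sub$proportion))
  out <- list()
  for (metric in c("sensitivity", "auc", "kappa")) {
    block <- data.frame(metric = metric,
                        proportion = c(format(props), "Average"),
                        stringsAsFactors = FALSE)
    for (m in methods) {
      col <- vapply(props, function(p)
        sub[[metric]][sub$method == m & sub$proportion == p][1], numeric(1))
      block[[m]] <- sprintf("%.3f", c(col, mean(col)))
    }
    out[[metric]] <- block
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
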