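#' Imputation configuration
#'
#' Bundles the fixed parameters and hyperparameter grids used by the eight
#' imputation methods. Defaults are the canonical study settings:
#' k = 10 neighbours; MICE with m = 20 chains of 50 iterations and a
#' 5-donor pool; random forests of 500 trees with `mtry` searched over
#' 1..8; single-hidden-layer networks with size 1..24 and weight decay in
#' \{0, 0.1, 0.01, 5e-4\}; RBF-kernel SVMs with cost in
#' \{0.25, 0.5, 1, 2, 4, 8, 16, 32\} and the bandwidth set automatically by
#' the median-pairwise-distance heuristic; grids searched by stratified
#' 10-fold cross-validation maximizing AUC.
#'
#' `fast = TRUE` switches to a reduced profile for desk-scale runs:
#' 5-fold CV, 100 trees, MICE m = 5 / 10 iterations, and coarser grids
#' (`mtry` \{1, 4, 8\}; size \{2, 8\} x decay \{0, 0.1\}; cost
#' \{0.25, 2, 16\}).
#'
#' @param fast Use the reduced profile.
#' @param seed Integer master seed for all imputer randomness.
#' @param ... Named overrides of any field.
#' @return An `imputer_config` list.
#' @export
imputer_config <- function(fast = FALSE, seed = 1L, ...) {
  cfg <- list(
    knn_k = 10L,
    mice_m = 20L, mice_maxit = 50L, mice_donors = 5L,
    rf_ntree = 500L,
    folds = 10L,
    nn_maxit = 200L,
    grids = list(
      rf  = data.frame(mtry = 1:8),
      nn  = expand.grid(size = 1:24, decay = c(0, 0.1, 0.01, 5e-4)),
      svm = data.frame(C = c(0.25, 0.5, 1, 2, 4, 8, 16, 32))
    ),
    seed = as.integer(seed),
    fast = isTRUE(fast)
  )
  if (isTRUE(fast)) {
    cfg$folds <- 5L
    cfg$rf_ntree <- 100L
    cfg$mice_m <- 5L; cfg$mice_maxit <- 10L
    cfg$nn_maxit <- 150L
    cfg$grids <- list(
      rf  = data.frame(mtry = c(1L, 4L, 8L)),
      nn  = expand.grid(size = c(2L, 8L), decay = c(0, 0.1)),
      svm = data.frame(C = c(0.25, 2, 16))
    )
  }
  override <- list(...)
  for (nm in names(override)) cfg[[nm]] <- override[[nm]]
  stopifnot(cfg$knn_k > 0, cfg$mice_m > 0, cfg$mice_maxit > 0,
            cfg$mice_donors > 0, cfg$rf_ntree > 0, cfg$folds >= 2,
            nrow(cfg$grids$rf) > 0, nrow(cfg$grids$nn) > 0,
            nrow(cfg$grids$svm) > 0)
  structure(cfg, class = "imputer_config")
}

#' Names of the eight imputation methods
#'
#' `MODE`, `KNN`, `MICE_PMM` are the traditional methods; `LR`, `RF`, `NN`,
#' `SVM` are single machine-learning classifiers; `EL` is the stacking
#' ensemble of the four.
#'
#' @return Character vector of method identifiers.
#' @export
imputation_methods <- function() {
  c("MODE", "KNN", "MICE_PMM", "LR", "RF", "NN", "SVM", "EL")
}

# completed-cohort constructor shared by all imputers
new_completed <- function(data, incomplete, method, tuned = NULL) {
  stopifnot(!anyNA(data[[target_variable()]]))
  validate_cohort(data, allow_missing = FALSE)
  structure(list(data = data,
                 method = method,
                 scenario = incomplete$scenario,
                 imputed = incomplete$mask,
                 tuned = tuned),
            class = "completed_cohort")
}

#' @export
print.completed_cohort <- function(x, ...) {
  cat(sprintf("<completed_cohort> n=%d method=%s imputed=%d cells\n",
              nrow(x$data), x$method, sum(x$imputed)))
  invisible(x)
}
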