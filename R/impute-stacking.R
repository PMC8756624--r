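#' Stacked-generalization ensemble imputation
#'
#' Two-stage stacking over the four classifier imputers. The first stage
#' tunes LR, RF, NN and SVM (reusing `tuned` models when supplied) and
#' builds, via one shared stratified k-fold split of the complete cases, the
#' meta-training matrix of out-of-fold class-1 probabilities (one column per
#' first-stage model). The second stage is an RBF-kernel SVM trained on
#' those four probability features, its cost tuned on the same grid and
#' folds; its bandwidth uses the median-pairwise-distance heuristic on the
#' meta features. For the missing records, the first-stage models are refit
#' on all complete cases, their probabilities form the meta input, and the
#' meta-SVM's predicted class is imputed.
#'
#' Out-of-fold (rather than resubstitution) first-stage predictions are used
#' so the meta-learner does not inherit the base learners' overfitting.
#'
#' @param incomplete An `incomplete_cohort`.
#' @param config An [imputer_config()].
#' @param tuned Optional named list of pre-tuned first-stage models
#'   (`LR`, `RF`, `NN`, `SVM`), e.g. from a prior [tune_classifier()] pass.
#' @return A `completed_cohort`; its `tuned` field carries the first-stage
#'   models and the selected meta cost.
#' @export
impute_stacking <- function(incomplete, config = imputer_config(),
                            tuned = NULL) {
  mask <- incomplete$mask
  if (!any(mask))
    return(new_completed(incomplete$data, incomplete, "EL"))
  stage_methods <- c("LR", "RF", "NN", "SVM")
  levs <- cohort_variables()[[target_variable()]]

  sub <- incomplete$data[!mask, , drop = FALSE]
  y <- factor(as.character(sub[[target_variable()]]), levels = levs)
  if (nlevels(droplevels(y)) < 2)
    stop("complete cases must contain both target classes")
  folds <- stratified_folds(y, config$folds, derive_seed(config$seed, 77L))

  if (is.null(tuned)) tuned <- list()
  for (m in stage_methods) {
    if (is.null(tuned[[m]]))
      tuned[[m]] <- tune_classifier(incomplete, m, config, folds = folds)
  }

  # out-of-fold meta-training features on the shared split
  n_c <- nrow(sub)
  meta <- matrix(NA_real_, n_c, length(stage_methods),
                 dimnames = list(NULL, stage_methods))
  designs <- lapply(stage_methods, function(m) learner_design(m, sub))
  names(designs) <- stage_methods
  for (fi in seq_along(folds)) {
    hold <- folds[[fi]]
    for (m in stage_methods) {
      X <- designs[[m]]
      fit <- fit_learner(m, X[-hold, , drop = FALSE], y[-hold],
                         tuned[[m]]$params, config,
                         seed = derive_seed(config$seed, 900L + 10L * fi +
                                              match(m, stage_methods)))
      meta[hold, m] <- predict_prob(fit, X[hold, , drop = FALSE])
    }
  }

  # second stage: RBF-SVM on the meta features, cost tuned on the same folds
  sigma_meta <- median_sigma(meta)
  costs <- sort(config$grids$svm$C)
  meta_auc <- vapply(seq_along(costs), function(ci) {
    mean(vapply(seq_along(folds), function(fi) {
      hold <- folds[[fi]]
      fit <- fit_learner("SVM", meta[-hold, , drop = FALSE], y[-hold],
                         list(C = costs[ci], sigma = sigma_meta), config,
                         seed = derive_seed(config$seed, 2000L + 50L * ci + fi))
      auc_rank(predict_prob(fit, meta[hold, , drop = FALSE]),
               y[hold] == levs[2])
    }, numeric(1)))
  }, numeric(1))
  meta_C <- costs[which.max(meta_auc)]
  meta_fit <- fit_learner("SVM", meta, y,
                          list(C = meta_C, sigma = sigma_meta), config,
                          seed = derive_seed(config$seed, 3000L))

  # first-stage refits on all complete cases, applied to the missing records
  miss_meta <- matrix(NA_real_, sum(mask), length(stage_methods),
                      dimnames = list(NULL, stage_methods))
  for (m in stage_methods) {
    X_all <- learner_design(m, incomplete$data)
    fit <- fit_learner(m, X_all[!mask, , drop = FALSE], y,
                       tuned[[m]]$params, config,
                       seed = derive_seed(config$seed, 4000L +
                                            match(m, stage_methods)))
    miss_meta[, m] <- predict_prob(fit, X_all[mask, , drop = FALSE])
  }
  prob <- predict_prob(meta_fit, miss_meta)
  data <- incomplete$data
  data[[target_variable()]][mask] <- prob_to_class(prob, levs)
  new_completed(data, incomplete, "EL",
                tuned = list(stage = tuned, meta_C = meta_C,
                             meta_sigma = sigma_meta,
                             meta_cv_auc = data.frame(C = costs,
                                                      mean_auc = meta_auc)))
}

#' Dispatch an imputation method by name
#'
#' Convenience front-end mapping a method identifier from
#' [imputation_methods()] to the corresponding imputer.
#'
#' @param incomplete An `incomplete_cohort`.
#' @param method Method identifier.
#' @param config An [imputer_config()].
#' @param tuned Optional pre-tuned model(s): a `tuned_model` for single
#'   classifiers, or a named list of them for `"EL"`.
#' @return A `completed_cohort`.
#' @export
impute_with <- function(incomplete, method, config = imputer_config(),
                        tuned = NULL) {
  method <- match.arg(method, imputation_methods())
  switch(method,
    MODE = impute_mode(incomplete),
    KNN = impute_knn(incomplete, config),
    MICE_PMM = impute_mice_pmm(incomplete, config),
    EL = impute_stacking(incomplete, config, tuned = tuned),
    {
      if (is.null(tuned)) tuned <- tune_classifier(incomplete, method, config)
      impute_classifier(incomplete, tuned, config)
    })
}
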