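# Model-family backends behind the classifier imputers.
#
# Each backend exposes fit_learner(method, X, y, params, config, seed) and
# predict_prob(fit, X): the probability of the SECOND-listed target category.
# Encodings follow each family's convention: one-hot + unit-variance scaling
# for LR/NN/SVM, ordinal codes for RF (8 unexpanded predictors).

learner_scheme <- function(method) {
  switch(method, RF = "ordinal",
         LR = , NN = , SVM = , EL = "onehot",
         stop("unknown method: ", method))
}

# intercept-bearing regression fits need treatment coding; distance- and
# margin-based learners keep the full one-hot block
learner_design <- function(method, cohort) {
  scheme <- learner_scheme(method)
  build_design(cohort, scheme, scale = (scheme == "onehot"),
               drop_first = (method == "LR"))
}

fit_learner <- function(method, X, y, params, config, seed) {
  stopifnot(is.factor(y), nlevels(y) == 2)
  restore <- local_rng(seed)
  on.exit(restore())
  y01 <- as.integer(y) - 1L
  fit <- switch(
    method,
    LR = {
      f <- ridge_logit(X, y01, lambda = 0)
      if (any(f$fitted > 1 - 1e-8 & y01 == 1) &&
          any(f$fitted < 1e-8 & y01 == 0) &&
          max(abs(f$coef)) > 1e3) {
        warning("separation in logistic imputation model; ridge fallback")
        f <- ridge_logit(X, y01, lambda = 1e-3)
      }
      list(kind = "LR", fit = f)
    },
    RF = {
      mtry <- min(params$mtry, ncol(X))
      list(kind = "RF",
           fit = randomForest::randomForest(
             x = as.data.frame(X), y = y,
             ntree = config$rf_ntree, mtry = mtry))
    },
    NN = {
      f <- nnet::nnet(x = X, y = y01, size = params$size,
                      decay = params$decay, entropy = TRUE,
                      maxit = config$nn_maxit, trace = FALSE,
                      MaxNWts = 5000)
      list(kind = "NN", fit = f)
    },
    SVM = {
      sigma <- if (!is.null(params$sigma)) params$sigma else median_sigma(X)
      f <- kernlab::ksvm(x = X, y = y, type = "C-svc", kernel = "rbfdot",
                         kpar = list(sigma = sigma), C = params$C,
                         prob.model = TRUE, scaled = FALSE)
      # orientation for the decision-value fallback when Platt scaling is
      # unavailable: flip so the second level gets the larger score
      dec <- as.numeric(kernlab::predict(f, X, type = "decision"))
      flip <- mean(dec[y01 == 1]) < mean(dec[y01 == 0])
      list(kind = "SVM", fit = f, flip = flip, levels = levels(y))
    },
    stop("unknown method: ", method)
  )
  fit$levels <- levels(y)
  fit
}

predict_prob <- function(fit, X) {
  switch(
    fit$kind,
    LR = predict_ridge_logit(fit$fit, X),
    RF = unname(
      stats::predict(fit$fit, as.data.frame(X), type = "prob")[, fit$levels[2]]),
    NN = as.numeric(stats::predict(fit$fit, X)),
    SVM = {
      p <- tryCatch(
        kernlab::predict(fit$fit, X, type = "probabilities")[, fit$levels[2]],
        error = function(e) NULL)
      if (is.null(p)) {
        dec <- as.numeric(kernlab::predict(fit$fit, X, type = "decision"))
        p <- stats::plogis(if (fit$flip) -dec else dec)
      }
      as.numeric(p)
    }
  )
}

# class prediction from a probability; exactly 0.5 breaks to the first level
prob_to_class <- function(prob, levels) {
  factor(levels[(prob > 0.5) + 1L], levels = levels)
}

#' Tune a classifier imputer by grid-searched cross-validation
#'
#' Runs stratified k-fold cross-validation on the complete cases (target
#' variable as label, all other variables including the outcome as
#' features) over the method's hyperparameter grid, and selects the grid
#' point with the maximal mean held-out AUC. Ties break toward the simpler
#' model: smaller `mtry`/`size`/cost, larger weight decay. `LR` has no
#' tunable hyperparameters and is returned as-is with an empty grid.
#'
#' @param incomplete An `incomplete_cohort`.
#' @param method `"LR"`, `"RF"`, `"NN"` or `"SVM"`.
#' @param config An [imputer_config()].
#' @param folds Optional pre-built list of held-out index vectors (into the
#'   complete cases); built from `config` when omitted.
#' @return A `tuned_model`: method, selected `params`, the `cv_table` of
#'   mean AUC per grid point, the fold list and the fold seed.
#' @export
tune_classifier <- function(incomplete, method = c("LR", "RF", "NN", "SVM"),
                            config = imputer_config(), folds = NULL) {
  method <- match.arg(method)
  mask <- incomplete$mask
  sub <- incomplete$data[!mask, , drop = FALSE]
  y <- droplevels(sub[[target_variable()]])
  if (nlevels(y) < 2)
    stop("complete cases must contain both target classes")
  y <- factor(as.character(y), levels = cohort_variables()[[target_variable()]])

  fold_seed <- derive_seed(config$seed, 7L)
  if (is.null(folds)) folds <- stratified_folds(y, config$folds, fold_seed)

  if (method == "LR") {
    return(structure(list(method = method, params = list(),
                          cv_table = data.frame(), folds = folds,
                          fold_seed = fold_seed),
                     class = "tuned_model"))
  }

  grid <- switch(method, RF = config$grids$rf,
                 NN = config$grids$nn, SVM = config$grids$svm)
  # order so the first argmax is the simplest configuration
  grid <- switch(method,
    RF  = grid[order(grid$mtry), , drop = FALSE],
    NN  = grid[order(grid$size, -grid$decay), , drop = FALSE],
    SVM = grid[order(grid$C), , drop = FALSE])
  X <- learner_design(method, sub)
  if (method == "SVM") sigma <- median_sigma(X)

  mean_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    if (method == "SVM") params$sigma <- sigma
    aucs <- vapply(seq_along(folds), function(fi) {
      hold <- folds[[fi]]
      fit <- fit_learner(method, X[-hold, , drop = FALSE], y[-hold],
                         params, config,
                         seed = derive_seed(config$seed, 100L * g + fi))
      auc_rank(predict_prob(fit, X[hold, , drop = FALSE]),
               y[hold] == levels(y)[2])
    }, numeric(1))
    mean_auc[g] <- mean(aucs)
  }
  best <- which.max(mean_auc)
  params <- as.list(grid[best, , drop = FALSE])
  if (method == "SVM") params$sigma <- sigma
  structure(list(method = method, params = params,
                 cv_table = cbind(grid, mean_auc = mean_auc,
                                  deparse.level = 0),
                 folds = folds, fold_seed = fold_seed),
            class = "tuned_model")
}

#' @export
print.tuned_model <- function(x, ...) {
  cat("<tuned_model>", x$method)
  if (length(x$params))
    cat(" |", paste(names(x$params),
                    vapply(x$params, function(p) format(p, digits = 4), ""),
                    sep = "=", collapse = " "))
  cat("\n")
  invisible(x)
}

#' Impute by a tuned classifier
#'
#' Fits the tuned method on all complete cases (target as label, the other
#' seven clinical variables plus the discharge outcome as features) and
#' assigns each missing cell the predicted class.
#'
#' @param incomplete An `incomplete_cohort`.
#' @param tuned A `tuned_model` from [tune_classifier()].
#' @param config An [imputer_config()].
#' @return A `completed_cohort`.
#' @export
impute_classifier <- function(incomplete, tuned,
                              config = imputer_config()) {
  mask <- incomplete$mask
  method <- tuned$method
  if (!any(mask))
    return(new_completed(incomplete$data, incomplete, method, tuned))
  X_all <- learner_design(method, incomplete$data)
  y <- incomplete$data[[target_variable()]]
  fit <- fit_learner(method, X_all[!mask, , drop = FALSE],
                     factor(y[!mask], levels = levels(y)),
                     tuned$params, config,
                     seed = derive_seed(config$seed, 500L + match(
                       method, c("LR", "RF", "NN", "SVM"))))
  prob <- predict_prob(fit, X_all[mask, , drop = FALSE])
  data <- incomplete$data
  data[[target_variable()]][mask] <- prob_to_class(prob, levels(y))
  new_completed(data, incomplete, method, tuned)
}
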