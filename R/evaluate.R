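#' Fit the discharge-prediction logistic model
#'
#' Maximum-likelihood binary logistic regression of discharge failure
#' (coded 1) on the eight clinical variables, fitted to the full (completed)
#' cohort with one-hot design and first-listed categories as reference
#' levels. Predictors that are constant in the data are dropped so the fit
#' degrades gracefully to an intercept-only model. On separation the model
#' is refit with a small ridge penalty and a warning.
#'
#' @param completed A `completed_cohort` or a complete cohort data frame.
#' @param epsilon,maxit Convergence tolerance and iteration cap.
#' @return An `outcome_model`: list with `coef`, `fitted` probabilities and
#'   the variables used.
#' @export
fit_outcome_model <- function(completed, epsilon = 1e-8, maxit = 100) {
  df <- if (inherits(completed, "completed_cohort")) completed$data
        else completed
  validate_cohort(df, allow_missing = FALSE)
  y <- df[[outcome_variable()]]
  if (length(unique(y)) < 2) stop("outcome has a single class")
  vars <- names(cohort_variables())
  used <- vars[vapply(vars, function(v)
    length(unique(as.character(df[[v]]))) > 1, logical(1))]
  if (length(used) == 0) {
    p <- mean(y)
    return(structure(list(coef = c(`(Intercept)` = stats::qlogis(p)),
                          fitted = rep(p, length(y)), variables = character()),
                     class = "outcome_model"))
  }
  fml <- stats::as.formula(paste(outcome_variable(), "~",
                                 paste(used, collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = epsilon,
                                            maxit = maxit)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || !fit$converged) {
    warning("separation in the outcome model; ridge-penalized fit used")
    X <- stats::model.matrix(fml, df)[, -1, drop = FALSE]
    rf <- ridge_logit(X, y, lambda = 1e-3, maxit = maxit, tol = epsilon)
    return(structure(list(coef = rf$coef, fitted = rf$fitted,
                          variables = used, ridge = TRUE),
                     class = "outcome_model"))
  }
  structure(list(coef = stats::coef(fit),
                 fitted = as.numeric(stats::fitted(fit)),
                 variables = used, ridge = FALSE),
            class = "outcome_model")
}

#' Decision-impact metrics of a predicted probability vector
#'
#' Confusion counts are taken at `threshold` with discharge failure as the
#' positive class. Sensitivity is TP / (TP + FN); Cohen's kappa is
#' (p_o - p_e) / (1 - p_e) with p_o = (TP + TN) / n and
#' p_e = \[(TP+FN)(TP+FP) + (TN+FP)(TN+FN)\] / n^2; AUC is the probability
#' that a random positive outranks a random negative, ties counted one
#' half (rank formulation). Kappa is reported unclipped and may be
#' negative for worse-than-chance prediction.
#'
#' @param probabilities Numeric vector in \[0, 1\].
#' @param labels 0/1 vector (or logical / two-level factor), 1 = positive.
#' @param threshold Classification cutoff; predictions at or above it are
#'   positive. Default 0.5.
#' @return A `metric_set`: sensitivity, auc, kappa, p_o, p_e and the
#'   confusion counts (TP, FN, FP, TN).
#' @export
#' @examples
#' compute_metrics(c(0.9, 0.4, 0.8, 0.1), c(1, 1, 0, 0))
compute_metrics <- function(probabilities, labels, threshold = 0.5) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  stopifnot(length(probabilities) == length(labels),
            all(labels %in% c(0L, 1L)),
            all(probabilities >= 0 & probabilities <= 1))
  if (length(unique(labels)) < 2)
    stop("labels contain a single class")
  pred <- as.integer(probabilities >= threshold)
  TP <- sum(pred == 1L & labels == 1L)
  FN <- sum(pred == 0L & labels == 1L)
  FP <- sum(pred == 1L & labels == 0L)
  TN <- sum(pred == 0L & labels == 0L)
  n <- length(labels)
  p_o <- (TP + TN) / n
  p_e <- ((TP + FN) * (TP + FP) + (TN + FP) * (TN + FN)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 0
  structure(list(sensitivity = TP / (TP + FN),
                 auc = auc_rank(probabilities, labels == 1L),
                 kappa = kappa, p_o = p_o, p_e = p_e,
                 TP = TP, FN = FN, FP = FP, TN = TN,
                 threshold = threshold),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("sensitivity %.3f | AUC %.3f | kappa %.3f (threshold %.3g)\n",
              x$sensitivity, x$auc, x$kappa, x$threshold))
  invisible(x)
}

#' Youden-optimal classification threshold
#'
#' Returns the cutoff maximizing sensitivity + specificity - 1 over the
#' observed probabilities; ties break toward the lower cutoff (higher
#' sensitivity). Offered as an alternative to the default 0.5 cutoff for
#' imbalanced cohorts.
#'
#' @param probabilities,labels As in [compute_metrics()].
#' @return Numeric threshold.
#' @export
youden_threshold <- function(probabilities, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  cand <- sort(unique(probabilities))
  j <- vapply(cand, function(t) {
    sens <- sum(probabilities >= t & labels == 1L) / sum(labels == 1L)
    spec <- sum(probabilities < t & labels == 0L) / sum(labels == 0L)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Evaluate a completed cohort against the discharge model
#'
#' Fits the outcome model on the completed cohort and computes apparent
#' (resubstitution) metrics on the same records — the reference usage for
#' benchmarking imputation methods, since the question is how imputation
#' distorts the fitted decision model. A cross-validated alternative is
#' available via `cv_folds`.
#'
#' @param completed A `completed_cohort` or complete cohort data frame.
#' @param threshold Classification cutoff (default 0.5).
#' @param reference Optional `metric_set` of the original complete data,
#'   attached to the result.
#' @param cv_folds If > 1, metrics are computed on held-out folds instead
#'   of by resubstitution.
#' @return A `scenario_result`: method and scenario identifiers (when
#'   available), the `metrics`, and the `reference` metrics.
#' @export
evaluate_scenario <- function(completed, threshold = 0.5, reference = NULL,
                              cv_folds = 1) {
  df <- if (inherits(completed, "completed_cohort")) completed$data
        else completed
  y <- df[[outcome_variable()]]
  if (cv_folds > 1) {
    folds <- stratified_folds(factor(y), cv_folds, 1L)
    prob <- numeric(length(y))
    for (f in folds) {
      m <- fit_outcome_model(df[-f, , drop = FALSE])
      prob[f] <- predict_outcome(m, df[f, , drop = FALSE])
    }
  } else {
    model <- fit_outcome_model(df)
    prob <- model$fitted
  }
  metrics <- compute_metrics(prob, y, threshold)
  structure(list(
    method = if (inherits(completed, "completed_cohort")) completed$method
             else "reference",
    scenario = if (inherits(completed, "completed_cohort"))
                 completed$scenario else NULL,
    metrics = metrics, reference = reference),
    class = "scenario_result")
}

# probabilities from a fitted outcome model on new records
predict_outcome <- function(model, df) {
  if (length(model$variables) == 0)
    return(rep(stats::plogis(model$coef[1]), nrow(df)))
  fml <- stats::as.formula(paste("~", paste(model$variables,
                                            collapse = " + ")))
  X <- stats::model.matrix(fml, df)
  keep <- intersect(colnames(X), names(model$coef))
  eta <- drop(X[, keep, drop = FALSE] %*% model$coef[keep])
  stats::plogis(eta)
}

#' Average metrics over the proportion grid
#'
#' Unweighted arithmetic mean across proportions, the "Average"-row
#' summary of a benchmark table, reported at 3 decimals. Accepts either a
#' plain numeric series of one metric or a list of `scenario_result`s
#' sharing one mechanism and method.
#'
#' @param results Numeric vector, or list of `scenario_result` objects.
#' @return For a numeric input, the rounded mean; for results, a named
#'   numeric vector with `sensitivity`, `auc`, `kappa`.
#' @export
#' @examples
#' average_over_proportions(c(0.889, 0.881, 0.897, 0.889, 0.923, 0.969))
average_over_proportions <- function(results) {
  if (length(results) == 0) stop("empty results")
  if (is.numeric(results)) return(round(mean(results), 3))
  stopifnot(all(vapply(results, inherits, logical(1), "scenario_result")))
  vapply(c("sensitivity", "auc", "kappa"), function(m)
    round(mean(vapply(results, function(r) r$metrics[[m]], numeric(1))), 3),
    numeric(1))
}
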