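#' Mode imputation
#'
#' Fills every missing target cell with the modal category of the observed
#' target values; ties break toward the first-listed category.
#'
#' @param incomplete An `incomplete_cohort` from [ampute()].
#' @return A `completed_cohort`.
#' @export
impute_mode <- function(incomplete) {
  x <- incomplete$data[[target_variable()]]
  if (all(is.na(x))) stop("target column is entirely missing")
  data <- incomplete$data
  data[[target_variable()]][incomplete$mask] <- observed_mode(x)
  new_completed(data, incomplete, "MODE")
}

#' K-nearest-neighbour imputation
#'
#' For each record with a missing target value, computes Euclidean distances
#' on the one-hot encoded, unit-variance-scaled non-target variables
#' (outcome included) to every complete record, takes the `k` nearest
#' donors, and imputes the median of their 0/1 target codes. A median of
#' exactly 0.5 falls back to the overall observed mode; distance ties break
#' by record index, so the result is deterministic.
#'
#' @param incomplete An `incomplete_cohort`.
#' @param config An [imputer_config()] (uses `knn_k`, default 10).
#' @return A `completed_cohort`.
#' @export
impute_knn <- function(incomplete, config = imputer_config()) {
  k <- config$knn_k
  mask <- incomplete$mask
  n_complete <- sum(!mask)
  if (n_complete < k)
    stop("need at least k = ", k, " complete records, have ", n_complete)
  if (!any(mask)) return(new_completed(incomplete$data, incomplete, "KNN"))

  X <- build_design(incomplete$data, "onehot", scale = TRUE)
  donors_idx <- which(!mask)
  codes <- as.integer(incomplete$data[[target_variable()]]) - 1L
  overall_mode <- observed_mode(incomplete$data[[target_variable()]])
  levs <- cohort_variables()[[target_variable()]]

  data <- incomplete$data
  for (i in which(mask)) {
    d2 <- colSums((t(X[donors_idx, , drop = FALSE]) - X[i, ])^2)
    ord <- order(d2, donors_idx)[seq_len(k)]
    med <- stats::median(codes[donors_idx[ord]])
    data[[target_variable()]][i] <-
      if (med == 0.5) overall_mode else levs[(med > 0.5) + 1L]
  }
  new_completed(data, incomplete, "KNN")
}

#' MICE imputation with predictive mean matching
#'
#' Runs `m` independent chained-equation chains on the 0/1-coded target.
#' Each chain iterates `maxit` times: regression coefficients are drawn
#' from the approximate normal posterior of a (ridge-stabilized)
#' least-squares fit of the target code on the encoded predictors over the
#' complete cases; predictive means are computed for all records; each
#' missing record is matched to the `donors` observed records with the
#' closest predictive means and one donor's observed value is drawn at
#' random. The chains' final draws are averaged per cell and the average is
#' decoded as the second-listed category iff it is at least 0.5.
#'
#' Because only the one target variable is ever missing, iterations refresh
#' the posterior draw but the observed conditioning set is fixed; the full
#' iteration count is still executed so the chain settings are honoured.
#'
#' @param incomplete An `incomplete_cohort`.
#' @param config An [imputer_config()] (uses `mice_m`, `mice_maxit`,
#'   `mice_donors`, `seed`).
#' @return A `completed_cohort`.
#' @export
impute_mice_pmm <- function(incomplete, config = imputer_config()) {
  mask <- incomplete$mask
  if (!any(mask))
    return(new_completed(incomplete$data, incomplete, "MICE_PMM"))
  y_obs_fac <- incomplete$data[[target_variable()]][!mask]
  levs <- cohort_variables()[[target_variable()]]

  X <- build_design(incomplete$data, "onehot", scale = TRUE,
                    drop_first = TRUE)
  Xd <- cbind(1, X)
  y <- as.integer(incomplete$data[[target_variable()]]) - 1L
  obs <- which(!mask); mis <- which(mask)
  y_o <- y[obs]

  restore <- local_rng(derive_seed(config$seed, 31L))
  on.exit(restore())

  if (length(unique(y_o)) < 2) {
    # degenerate donor pool: every chain returns the single observed value
    data <- incomplete$data
    data[[target_variable()]][mis] <- levs[y_o[1] + 1L]
    return(new_completed(data, incomplete, "MICE_PMM"))
  }

  Xo <- Xd[obs, , drop = FALSE]
  p <- ncol(Xo)
  A <- crossprod(Xo)
  ridge <- 1e-8 * mean(diag(A))
  Ainv <- tryCatch(solve(A), error = function(e) {
    warning("singular imputation design; ridge-stabilized fit used")
    solve(A + diag(ridge * 1e6, p))
  })
  beta_hat <- drop(Ainv %*% crossprod(Xo, y_o))
  resid <- y_o - drop(Xo %*% beta_hat)
  df_res <- max(length(obs) - p, 1)
  yhat_obs <- drop(Xo %*% beta_hat)
  Xm <- Xd[mis, , drop = FALSE]
  R <- tryCatch(chol(Ainv), error = function(e) chol(Ainv + diag(1e-10, p)))

  draws <- matrix(0, nrow = length(mis), ncol = config$mice_m)
  for (chain in seq_len(config$mice_m)) {
    imp <- NULL
    for (it in seq_len(config$mice_maxit)) {
      sigma2 <- sum(resid^2) / stats::rchisq(1, df_res)
      beta_star <- beta_hat + sqrt(sigma2) * drop(t(R) %*% stats::rnorm(p))
      yhat_mis <- drop(Xm %*% beta_star)
      imp <- vapply(yhat_mis, function(mu) {
        d <- abs(yhat_obs - mu)
        pool <- order(d, seq_along(d))[seq_len(min(config$mice_donors,
                                                   length(d)))]
        y_o[pool[sample.int(length(pool), 1L)]]
      }, numeric(1))
    }
    draws[, chain] <- imp
  }
  avg <- rowMeans(draws)
  data <- incomplete$data
  data[[target_variable()]][mis] <- levs[(avg >= 0.5) + 1L]
  new_completed(data, incomplete, "MICE_PMM")
}
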