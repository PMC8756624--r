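# shared numerical helpers

# stratified k-fold assignment: returns list of held-out index vectors;
# errors if any fold would miss a class (caller may reduce k)
stratified_folds <- function(y, k, seed) {
  stopifnot(k >= 2)
  restore <- local_rng(seed)
  on.exit(restore())
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- rep_len(sample.int(k), length(idx))[sample.int(length(idx))]
  }
  folds <- lapply(seq_len(k), function(i) which(fold == i))
  for (f in folds) {
    if (length(unique(y[-f])) < 2 || length(f) == 0)
      stop("cross-validation fold missing a class; reduce the fold count")
  }
  folds
}

# AUC by the rank (Mann-Whitney) formulation, ties counted one half
auc_rank <- function(prob, positive) {
  positive <- as.logical(positive)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: labels contain a single class")
  r <- rank(prob)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# logistic regression by IRLS with an optional ridge penalty on the
# non-intercept coefficients; used directly for imputation fits and as the
# stabilizing fallback when the unpenalized likelihood separates
ridge_logit <- function(X, y, lambda = 0, maxit = 100, tol = 1e-8) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Xd * w)
    A <- XtW %*% Xd + pen
    beta_new <- tryCatch(solve(A, XtW %*% z),
                         error = function(e) solve(A + diag(1e-8, p),
                                                   XtW %*% z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  list(coef = drop(beta),
       fitted = stats::plogis(drop(Xd %*% beta)))
}

predict_ridge_logit <- function(fit, X) {
  stats::plogis(drop(cbind(1, X) %*% fit$coef))
}

# RBF bandwidth by the median-pairwise-squared-distance heuristic, on the
# kernlab parameterization k(x,y) = exp(-sigma * ||x-y||^2)
median_sigma <- function(X, max_rows = 500L) {
  n <- nrow(X)
  if (n > max_rows) {
    idx <- unique(as.integer(round(seq(1, n, length.out = max_rows))))
    X <- X[idx, , drop = FALSE]
  }
  d2 <- as.vector(stats::dist(X))^2
  d2 <- d2[d2 > 0]
  if (length(d2) == 0) return(1)
  1 / stats::median(d2)
}

# modal observed category; ties break toward the first-listed level
observed_mode <- function(x) {
  levs <- levels(x)
  cnt <- table(factor(x[!is.na(x)], levels = levs))
  levs[which.max(cnt)]
}
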