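test_that("confusion metrics follow the defining arithmetic", {
  # TP=90 FN=10 FP=20 TN=80 at threshold 0.5
  prob <- c(rep(0.9, 90), rep(0.1, 10), rep(0.9, 20), rep(0.1, 80))
  lab <- c(rep(1, 100), rep(0, 100))
  m <- compute_metrics(prob, lab)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$p_o, 0.85)
  expect_equal(m$p_e, 0.5)
  expect_equal(m$kappa, 0.7)
  expect_equal(c(m$TP, m$FN, m$FP, m$TN), c(90, 10, 20, 80))

  # perfect ranking and threshold
  p2 <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(c(p2$sensitivity, p2$auc, p2$kappa), c(1, 1, 1))

  # all-pairs AUC oracle: positives {0.9, 0.4}, negatives {0.8, 0.1}
  p3 <- compute_metrics(c(0.9, 0.4, 0.8, 0.1), c(1, 1, 0, 0))
  expect_equal(p3$auc, 3 / 4)
})

test_that("metrics agree with brute-force confusion and all-pairs oracles", {
  all_pairs_auc <- function(prob, lab) {
    pos <- prob[lab == 1]; neg <- prob[lab == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  for (s in 1:10) {
    set.seed(s)
    n <- sample(20:200, 1)
    lab <- rbinom(n, 1, 0.3)
    if (length(unique(lab)) < 2) next
    prob <- round(runif(n), 2)  # rounding forces ties
    thr <- runif(1)
    m <- compute_metrics(prob, lab, thr)
    pred <- as.integer(prob >= thr)
    expect_equal(m$TP, sum(pred & lab))
    expect_equal(m$sensitivity, sum(pred & lab) / sum(lab))
    expect_equal(m$auc, all_pairs_auc(prob, lab))
    # kappa via explicit agreement proportions
    p_o <- mean(pred == lab)
    p_e <- mean(pred) * mean(lab) + mean(1 - pred) * mean(1 - lab)
    expect_equal(m$kappa, (p_o - p_e) / (1 - p_e))
  }
})

test_that("AUC matches an established ROC implementation and is rank-invariant", {
  set.seed(2)
  lab <- rbinom(150, 1, 0.25)
  prob <- plogis(rnorm(150) + lab)
  m <- compute_metrics(prob, lab)
  expect_equal(m$auc,
               as.numeric(pROC::auc(pROC::roc(lab, prob, quiet = TRUE))))
  # invariance under a strictly monotone transform
  m2 <- compute_metrics(prob^3, lab)
  expect_equal(m2$auc, m$auc)
})

test_that("kappa is zero for label-independent predictions", {
  # constructed product table: prediction independent of label
  prob <- c(rep(1, 30), rep(0, 70), rep(1, 15), rep(0, 35))
  lab <- c(rep(0, 100), rep(1, 50))
  expect_equal(compute_metrics(prob, lab, 0.5)$kappa, 0)
})

test_that("sensitivity is non-increasing in the threshold", {
  set.seed(5)
  lab <- rbinom(120, 1, 0.3)
  prob <- runif(120)
  sens <- vapply(seq(0, 1, by = 0.05), function(t)
    compute_metrics(prob, lab, t)$sensitivity, numeric(1))
  expect_true(all(diff(sens) <= 1e-12))
})

test_that("the outcome model degrades to prevalence on a constant design", {
  coh <- generate_cohort(published_profile(), "exact", seed = 6)
  flat <- coh
  for (v in names(cohort_variables()))
    flat[[v]] <- factor(cohort_variables()[[v]][1],
                        levels = cohort_variables()[[v]])
  m <- fit_outcome_model(flat)
  expect_equal(unique(round(m$fitted, 10)), round(261 / 1468, 10))
  expect_equal(unname(m$coef[1]), log(261 / 1207), tolerance = 1e-8)
  # failure is the positive class: higher fitted risk for deep-coma cases
  full <- fit_outcome_model(coh)
  expect_gt(mean(full$fitted[coh$deep_coma == "yes"]),
            mean(full$fitted[coh$deep_coma == "no"]))
})

test_that("a perfectly separating predictor orders the strata monotonically", {
  coh <- toy_cohort(40, deep_coma = rep(c("no", "yes"), each = 20),
                    outcome = rep(0:1, each = 20))
  m <- suppressWarnings(fit_outcome_model(coh))
  expect_gt(min(m$fitted[coh$deep_coma == "yes"]),
            max(m$fitted[coh$deep_coma == "no"]))
})

test_that("evaluating the untouched cohort reproduces the reference exactly", {
  coh <- generate_cohort(published_profile(), "exact", seed = 6)
  ref <- evaluate_scenario(coh)$metrics
  inc <- ampute(coh, missing_scenario("MCAR", 0, 1))
  out <- impute_mode(mask_cohort(coh, integer(0)))
  ev <- evaluate_scenario(out, reference = ref)
  expect_equal(ev$metrics$sensitivity, ref$sensitivity)
  expect_equal(ev$metrics$auc, ref$auc)
  expect_equal(ev$metrics$kappa, ref$kappa)
  expect_identical(ev$reference, ref)
})

test_that("metrics converge to the reference as the missing proportion vanishes", {
  coh <- generate_cohort(published_profile(), "exact", seed = 6)
  ref <- evaluate_scenario(coh)$metrics
  cfg <- imputer_config(fast = TRUE, seed = 2)
  inc <- ampute(coh, missing_scenario("MCAR", 0.001, 4))
  expect_equal(sum(inc$mask), 1)
  for (m in imputation_methods()) {
    ev <- evaluate_scenario(impute_with(inc, m, cfg))
    expect_equal(ev$metrics$sensitivity, ref$sensitivity,
                 tolerance = 5e-3, info = m)
    expect_equal(ev$metrics$auc, ref$auc, tolerance = 5e-3, info = m)
    expect_equal(ev$metrics$kappa, ref$kappa, tolerance = 5e-3, info = m)
  }
})

test_that("proportion averaging is the unweighted 3-decimal mean", {
  expect_equal(average_over_proportions(c(0.889, 0.881, 0.897,
                                          0.889, 0.923, 0.969)), 0.908)
  expect_equal(average_over_proportions(rep(0.42, 6)), 0.42)
  expect_equal(average_over_proportions(c(0, 1)), 0.5)
  expect_error(average_over_proportions(numeric(0)), "empty")
})

test_that("the Youden threshold maximizes sensitivity + specificity - 1", {
  set.seed(9)
  lab <- rbinom(200, 1, 0.2)
  prob <- plogis(rnorm(200, mean = 2 * lab - 1))
  t_star <- youden_threshold(prob, lab)
  j <- function(t) {
    m <- compute_metrics(prob, lab, t)
    m$sensitivity + (m$TN / (m$TN + m$FP)) - 1
  }
  grid <- sort(unique(prob))
  expect_equal(j(t_star), max(vapply(grid, j, numeric(1))))
})
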