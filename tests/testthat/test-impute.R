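cfg_fast <- imputer_config(fast = TRUE, seed = 7)

test_that("mode imputation fills with the observed majority, ties to first level", {
  coh <- toy_cohort(13, volume_ge30ml = c(rep("<30ml", 10), rep(">=30ml", 3)))
  inc <- mask_cohort(coh, 11:13)  # observed 10 vs 0
  out <- impute_mode(inc)
  expect_true(all(out$data$volume_ge30ml[11:13] == "<30ml"))

  tie <- toy_cohort(12, volume_ge30ml = rep(c("<30ml", ">=30ml"), 5))
  inc_tie <- mask_cohort(tie, 11:12)  # observed 5 vs 5
  expect_true(all(impute_mode(inc_tie)$data$volume_ge30ml[11:12] == "<30ml"))

  # no missing cells: identity
  full <- mask_cohort(coh, integer(0))
  expect_equal(as.data.frame(impute_mode(full)$data), as.data.frame(coh))
  # all-missing target errors
  expect_error(impute_mode(mask_cohort(coh, 1:13)), "entirely missing")
})

test_that("KNN matches a brute-force nearest-neighbour oracle", {
  knn_oracle <- function(inc, k) {
    X <- imputeImpact:::build_design(inc$data, "onehot", scale = TRUE)
    levs <- cohort_variables()[[target_variable()]]
    codes <- as.integer(inc$data[[target_variable()]]) - 1L
    donors <- which(!inc$mask)
    out <- inc$data[[target_variable()]]
    ov_mode <- imputeImpact:::observed_mode(out)
    for (i in which(inc$mask)) {
      d <- sqrt(rowSums(sweep(X[donors, , drop = FALSE], 2, X[i, ])^2))
      sel <- donors[order(d, donors)][seq_len(k)]
      med <- stats::median(codes[sel])
      out[i] <- if (med == 0.5) ov_mode else levs[(med > 0.5) + 1L]
    }
    out
  }
  for (seed in 1:4) {
    coh <- coupled_cohort(n = 50, seed = seed)
    inc <- ampute(coh, missing_scenario("MCAR", 0.3, seed))
    got <- impute_knn(inc, cfg_fast)$data[[target_variable()]]
    expect_equal(as.character(got),
                 as.character(knn_oracle(inc, cfg_fast$knn_k)),
                 info = paste("seed", seed))
  }
})

test_that("KNN zero-distance donors dominate and k defaults to 10", {
  expect_equal(imputer_config()$knn_k, 10L)
  # 10 complete records identical to the missing one, all sharing one value
  coh <- toy_cohort(12, deep_coma = "yes",
                    volume_ge30ml = c(rep(">=30ml", 10), "<30ml", "<30ml"),
                    outcome = 1L)
  coh$deep_coma[11] <- "no"; coh$volume_ge30ml[11] <- "<30ml"
  inc <- mask_cohort(coh, 12)
  out <- impute_knn(inc, imputer_config(seed = 1))
  expect_equal(as.character(out$data$volume_ge30ml[12]), ">=30ml")
  # fewer complete records than k errors
  small <- toy_cohort(8)
  expect_error(impute_knn(mask_cohort(small, 1), imputer_config()),
               "at least k")
})

test_that("MICE-PMM honours its defaults and degenerate donor pools", {
  cfg <- imputer_config()
  expect_equal(cfg$mice_m, 20L)
  expect_equal(cfg$mice_maxit, 50L)
  expect_equal(cfg$mice_donors, 5L)
  # constant observed target: every chain returns that value
  coh <- toy_cohort(30, volume_ge30ml = "<30ml")
  inc <- mask_cohort(coh, 1:5)
  out <- impute_mice_pmm(inc, cfg_fast)
  expect_true(all(out$data$volume_ge30ml[1:5] == "<30ml"))
})

test_that("MICE-PMM recovers a target perfectly determined by a predictor", {
  # target is an exact copy of deep_coma within a separable toy cohort
  coh <- toy_cohort(60, deep_coma = rep(c("no", "yes"), 30),
                    volume_ge30ml = rep(c("<30ml", ">=30ml"), 30),
                    outcome = rep(0:1, each = 30))
  inc <- mask_cohort(coh, seq(2, 40, by = 2))
  # constant toy columns make the design singular: signalled, not fatal
  expect_warning(out <- impute_mice_pmm(inc, imputer_config(seed = 3)),
                 "ridge-stabilized")
  expect_equal(imputation_accuracy(out, inc), 1)
})

test_that("classifier imputers learn an exact predictor copy perfectly", {
  # balanced classes; uninformative variables vary randomly so no
  # predictor is degenerate
  set.seed(30)
  n <- 120
  coh <- toy_cohort(n, deep_coma = rep(c("no", "yes"), n / 2),
                    operation = sample(c("no", "yes"), n, replace = TRUE),
                    age = sample(cohort_variables()$age, n, replace = TRUE),
                    gender = sample(c("male", "female"), n, replace = TRUE),
                    co_infection = sample(c("no", "yes"), n, replace = TRUE),
                    location = sample(c("deep", "superficial"), n,
                                      replace = TRUE),
                    volume_ge30ml = rep(c("<30ml", ">=30ml"), n / 2),
                    outcome = rep(0:1, n / 2))
  inc <- mask_cohort(coh, 101:120)   # ten missing cells per class
  for (m in c("LR", "RF", "NN", "SVM", "EL")) {
    cfg <- imputer_config(fast = TRUE, seed = 11, folds = 4L)
    out <- impute_with(inc, m, cfg)
    expect_equal(imputation_accuracy(out, inc), 1, info = m)
  }
})

test_that("LR imputation reproduces stratum rates of a 2x2 table", {
  # one informative binary predictor; logistic fit on a 2x2 table predicts
  # the majority class within each predictor stratum (closed form)
  set.seed(41)
  n <- 200
  dc <- rep(c("no", "yes"), each = n / 2)
  vol <- ifelse(dc == "yes",
                ifelse(runif(n / 2) < 0.8, ">=30ml", "<30ml"),
                ifelse(runif(n / 2) < 0.25, ">=30ml", "<30ml"))
  coh <- toy_cohort(n, deep_coma = dc, volume_ge30ml = vol, outcome = 0:1)
  inc <- mask_cohort(coh, seq(5, n, by = 10))
  tuned <- tune_classifier(inc, "LR", cfg_fast)
  out <- impute_classifier(inc, tuned, cfg_fast)
  obs <- inc$data[!inc$mask, ]
  for (i in which(inc$mask)) {
    stratum <- obs[obs$deep_coma == coh$deep_coma[i], ]
    maj <- names(which.max(table(stratum$volume_ge30ml)))
    expect_equal(as.character(out$data$volume_ge30ml[i]), maj)
  }
})

test_that("grid search selects the mean-CV-AUC argmax with simplest-first ties", {
  expect_equal(imputer_config()$grids$svm$C,
               c(0.25, 0.5, 1, 2, 4, 8, 16, 32))
  expect_equal(imputer_config()$grids$rf$mtry, 1:8)
  coh <- coupled_cohort(n = 200, seed = 9)
  inc <- ampute(coh, missing_scenario("MCAR", 0.3, 2))
  cfg <- imputer_config(fast = TRUE, seed = 5)
  tuned <- tune_classifier(inc, "SVM", cfg)
  tab <- tuned$cv_table
  expect_equal(tuned$params$C, tab$C[which.max(tab$mean_auc)])
  expect_equal(max(tab$mean_auc),
               tab$mean_auc[tab$C == tuned$params$C])
  # independent re-evaluation of the recorded grid with the same folds
  sub <- inc$data[!inc$mask, ]
  y <- factor(as.character(sub[[target_variable()]]),
              levels = cohort_variables()[[target_variable()]])
  X <- imputeImpact:::learner_design("SVM", sub)
  sigma <- imputeImpact:::median_sigma(X)
  for (g in seq_len(nrow(tab))) {
    aucs <- vapply(seq_along(tuned$folds), function(fi) {
      hold <- tuned$folds[[fi]]
      fit <- imputeImpact:::fit_learner(
        "SVM", X[-hold, , drop = FALSE], y[-hold],
        list(C = tab$C[g], sigma = sigma), cfg,
        seed = imputeImpact:::derive_seed(cfg$seed, 100L * g + fi))
      imputeImpact:::auc_rank(
        imputeImpact:::predict_prob(fit, X[hold, , drop = FALSE]),
        y[hold] == levels(y)[2])
    }, numeric(1))
    expect_equal(mean(aucs), tab$mean_auc[g], tolerance = 1e-10)
  }
  # single-point grid: that point is selected; LR returns an empty grid
  cfg1 <- imputer_config(fast = TRUE, seed = 5,
                         grids = list(rf = data.frame(mtry = 3L),
                                      nn = imputer_config(fast = TRUE)$grids$nn,
                                      svm = imputer_config(fast = TRUE)$grids$svm))
  expect_equal(tune_classifier(inc, "RF", cfg1)$params$mtry, 3L)
  expect_equal(tune_classifier(inc, "LR", cfg)$params, list())
})

test_that("stacking builds a four-column out-of-fold meta problem", {
  coh <- toy_cohort(80, deep_coma = rep(c("no", "yes"), 40),
                    volume_ge30ml = rep(c("<30ml", ">=30ml"), 40),
                    outcome = rep(0:1, each = 40))
  inc <- mask_cohort(coh, seq(4, 72, by = 4))
  cfg <- imputer_config(fast = TRUE, seed = 13, folds = 4L)
  out <- impute_stacking(inc, cfg)
  expect_named(out$tuned$stage, c("LR", "RF", "NN", "SVM"))
  expect_equal(length(out$tuned$stage), 4)
  # separable consensus: all stage models agree, so the ensemble does too
  expect_equal(imputation_accuracy(out, inc), 1)
  expect_s3_class(out$tuned$meta_cv_auc, "data.frame")
})

test_that("all imputers complete the cohort, touch only the target, deterministically", {
  coh <- coupled_cohort(n = 200, seed = 21)
  inc <- ampute(coh, missing_scenario("MAR_2_1", 0.3, 3))
  others <- setdiff(names(coh), target_variable())
  for (m in imputation_methods()) {
    cfg <- imputer_config(fast = TRUE, seed = 17)
    a <- impute_with(inc, m, cfg)
    expect_false(anyNA(a$data[[target_variable()]]), info = m)
    expect_true(all(a$data[[target_variable()]] %in%
                      cohort_variables()[[target_variable()]]), info = m)
    expect_identical(as.data.frame(a$data)[others],
                     as.data.frame(coh)[others], info = m)
    # observed target cells are never altered
    expect_equal(as.character(a$data[[target_variable()]][!inc$mask]),
                 as.character(coh[[target_variable()]][!inc$mask]), info = m)
    b <- impute_with(inc, m, imputer_config(fast = TRUE, seed = 17))
    expect_identical(as.data.frame(a$data), as.data.frame(b$data), info = m)
  }
})

test_that("model-based imputers beat mode imputation on coupled data", {
  wins_lr <- 0L; wins_rf <- 0L
  for (s in 1:20) {
    coh <- coupled_cohort(n = 250, seed = 100 + s)
    inc <- ampute(coh, missing_scenario("MCAR", 0.3, s))
    cfg <- imputer_config(fast = TRUE, seed = s)
    acc_mode <- imputation_accuracy(impute_mode(inc), inc)
    tuned_lr <- tune_classifier(inc, "LR", cfg)
    acc_lr <- imputation_accuracy(impute_classifier(inc, tuned_lr, cfg), inc)
    tuned_rf <- tune_classifier(inc, "RF", cfg)
    acc_rf <- imputation_accuracy(impute_classifier(inc, tuned_rf, cfg), inc)
    wins_lr <- wins_lr + (acc_lr > acc_mode)
    wins_rf <- wins_rf + (acc_rf > acc_mode)
  }
  expect_gt(wins_lr, 10)
  expect_gt(wins_rf, 10)
})
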