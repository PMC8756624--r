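# fixture builders shared across the suite; everything is generated in code

# a small complete cohort with explicit column values; unspecified
# variables are recycled from simple defaults
toy_cohort <- function(n, ..., outcome = NULL) {
  vars <- cohort_variables()
  given <- list(...)
  cols <- list()
  defaults <- lapply(vars, function(levs) levs[1])
  for (v in names(vars)) {
    vals <- if (!is.null(given[[v]])) given[[v]] else defaults[[v]]
    cols[[v]] <- factor(rep_len(as.character(vals), n), levels = vars[[v]])
  }
  if (is.null(outcome)) outcome <- rep_len(c(0L, 1L), n)
  cols[[outcome_variable()]] <- as.integer(rep_len(outcome, n))
  structure(as.data.frame(cols), class = c("cohort", "data.frame"))
}

# an incomplete_cohort with an explicit mask over a complete toy cohort
mask_cohort <- function(cohort, mask_idx,
                        scenario = missing_scenario("MCAR", 0.1, 1L)) {
  mask <- rep(FALSE, nrow(cohort))
  mask[mask_idx] <- TRUE
  data <- cohort
  truth <- data[[target_variable()]]
  data[[target_variable()]][mask] <- NA
  structure(list(data = data, mask = mask, truth = truth,
                 scenario = scenario,
                 allocation = list(total = sum(mask))),
            class = "incomplete_cohort")
}

# stochastic cohort with strong within-group predictor-target coupling, so
# model-based imputers have signal to learn
coupled_cohort <- function(n = 300, seed = 1, strength = 2.5) {
  generate_cohort(published_profile(), mode = "stochastic", n = n,
                  dependence = list(list("deep_coma", "volume_ge30ml", strength),
                                    list("operation", "volume_ge30ml", 1.5)),
                  seed = seed)
}

# cell-level imputation accuracy of a completed cohort
imputation_accuracy <- function(completed, incomplete) {
  idx <- incomplete$mask
  mean(completed$data[[target_variable()]][idx] == incomplete$truth[idx])
}

# brute-force exact one-sided signed-rank p by enumerating all sign vectors
wilcoxon_brute <- function(x, y) {
  d <- (x - y); d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  hits <- 0L
  for (code in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(code)[1:n])
    if (sum(r[signs == 1L]) >= w_obs - 1e-9) hits <- hits + 1L
  }
  hits / 2^n
}
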