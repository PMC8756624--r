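#' Missing-data scenario constructors
#'
#' A scenario is a mechanism, a total missing proportion, and a seed.
#' Mechanisms:
#' * `MCAR` — cells to blank are drawn uniformly from the whole cohort.
#' * `MAR_1_2` — missingness depends on the discharge outcome: the failure
#'   group's missing *proportion* is half the success group's (ratio 1:2).
#' * `MAR_2_1` — the failure group's missing proportion is twice the
#'   success group's (ratio 2:1).
#'
#' The canonical grid crosses the three mechanisms with proportions
#' 5%, 10%, 15%, 20%, 30%, 50% — 18 scenarios; arbitrary proportions are
#' accepted.
#'
#' @param mechanism One of `"MCAR"`, `"MAR_1_2"`, `"MAR_2_1"`.
#' @param p Total missing proportion in (0, 1) (0 allowed: no missingness).
#' @param seed Integer seed for cell selection.
#' @return A `missing_scenario` list.
#' @export
missing_scenario <- function(mechanism = c("MCAR", "MAR_1_2", "MAR_2_1"),
                             p, seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.numeric(p), length(p) == 1, p >= 0, p <= 1)
  structure(list(mechanism = mechanism, p = p, seed = as.integer(seed)),
            class = "missing_scenario")
}

#' @export
print.missing_scenario <- function(x, ...) {
  cat(sprintf("<missing_scenario> %s p=%.3g seed=%d\n",
              x$mechanism, x$p, x$seed))
  invisible(x)
}

mechanism_ratio <- function(mechanism) {
  # ratio r = (failure missing proportion) / (success missing proportion)
  switch(mechanism, MAR_1_2 = 0.5, MAR_2_1 = 2, MCAR = NA_real_)
}

#' Allocate missing cells to outcome groups
#'
#' The total number of blanked cells is `round(p * n)`; this total is held
#' fixed in every mechanism. Under MAR the per-group missing proportions
#' must satisfy the 1:2 or 2:1 ratio as closely as integer rounding allows:
#' the success-group count is the rounded real-valued share and the failure
#' group takes the remainder. Under MCAR cells are drawn group-blind, so
#' only the total is returned.
#'
#' @param n_failure,n_success Outcome group sizes.
#' @param p Total missing proportion.
#' @param mechanism Scenario mechanism.
#' @return A list with `total` and, for MAR, integer `m_failure` and
#'   `m_success`.
#' @export
#' @examples
#' allocate_missing_counts(261, 1207, 0.30, "MAR_2_1")  # 133 / 307
allocate_missing_counts <- function(n_failure, n_success, p, mechanism) {
  stopifnot(n_failure > 0, n_success > 0, p >= 0, p <= 1)
  n <- n_failure + n_success
  total <- as.integer(round(p * n))
  if (mechanism == "MCAR")
    return(list(total = total))
  r <- mechanism_ratio(mechanism)
  # solve m_f/n_f = r * m_s/n_s with m_f + m_s = total
  m_s <- as.integer(round(total * n_success / (n_success + r * n_failure)))
  m_f <- total - m_s
  if (m_f < 0 || m_s < 0 || m_f > n_failure || m_s > n_success)
    stop(sprintf(
      "infeasible allocation: p=%.3g with ratio %s needs %d/%d failure and %d/%d success cells",
      p, mechanism, m_f, n_failure, m_s, n_success))
  list(total = total, m_failure = m_f, m_success = m_s)
}

#' Ampute the target variable of a complete cohort
#'
#' Blanks the allocated number of target-variable cells, sampled uniformly
#' without replacement — within each outcome group for MAR mechanisms,
#' across all records for MCAR. The original values are retained for audit.
#'
#' @param cohort A complete cohort data frame.
#' @param scenario A [missing_scenario()].
#' @return An `incomplete_cohort`: list with `data` (cohort with `NA` in the
#'   target column), logical `mask`, `truth` (the blanked values), and
#'   `scenario`.
#' @export
ampute <- function(cohort, scenario) {
  validate_cohort(cohort, allow_missing = FALSE)
  n <- nrow(cohort)
  y <- cohort[[outcome_variable()]]
  alloc <- allocate_missing_counts(sum(y == 1L), sum(y == 0L),
                                   scenario$p, scenario$mechanism)
  restore <- local_rng(scenario$seed)
  on.exit(restore())
  mask <- rep(FALSE, n)
  if (scenario$mechanism == "MCAR") {
    if (alloc$total > 0)
      mask[sample.int(n, alloc$total)] <- TRUE
  } else {
    idx_f <- which(y == 1L); idx_s <- which(y == 0L)
    if (alloc$m_failure > 0)
      mask[idx_f[sample.int(length(idx_f), alloc$m_failure)]] <- TRUE
    if (alloc$m_success > 0)
      mask[idx_s[sample.int(length(idx_s), alloc$m_success)]] <- TRUE
  }
  data <- cohort
  truth <- data[[target_variable()]]
  data[[target_variable()]][mask] <- NA
  structure(list(data = data, mask = mask, truth = truth,
                 scenario = scenario, allocation = alloc),
            class = "incomplete_cohort")
}

#' @export
print.incomplete_cohort <- function(x, ...) {
  cat(sprintf("<incomplete_cohort> n=%d missing=%d (%s p=%.3g)\n",
              nrow(x$data), sum(x$mask), x$scenario$mechanism, x$scenario$p))
  invisible(x)
}

#' Enumerate the scenario grid
#'
#' Cross product of mechanisms and proportions in mechanism-major,
#' proportion-minor order, each with a distinct seed derived
#' deterministically from `seed_base`.
#'
#' @param proportions Numeric vector of total missing proportions.
#' @param mechanisms Character vector of mechanisms.
#' @param seed_base Integer base seed.
#' @return List of `missing_scenario` objects (18 on the canonical grid).
#' @export
enumerate_scenarios <- function(proportions = c(0.05, 0.10, 0.15, 0.20, 0.30, 0.50),
                                mechanisms = c("MCAR", "MAR_1_2", "MAR_2_1"),
                                seed_base = 1L) {
  stopifnot(length(proportions) > 0, length(mechanisms) > 0)
  out <- list()
  for (i in seq_along(mechanisms)) {
    for (j in seq_along(proportions)) {
      seed <- derive_seed(seed_base, i * 1000L + j)
      out[[length(out) + 1L]] <-
        missing_scenario(mechanisms[i], proportions[j], seed)
    }
  }
  out
}

# deterministic child seed, kept within 32-bit integer range
derive_seed <- function(base, offset) {
  as.integer((as.double(base) * 48271 + as.double(offset) * 16807) %%
               2147483647)
}

#' Write an incomplete cohort with its scenario sidecar
#'
#' The cohort goes to `<path>` in the standard CSV dialect (empty target
#' cells); the scenario provenance (mechanism, proportion, seed, allocated
#' counts) goes to `<path>.json`.
#'
#' @param incomplete An `incomplete_cohort`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_incomplete <- function(incomplete, path) {
  write_cohort(incomplete$data, path)
  side <- list(mechanism = incomplete$scenario$mechanism,
               p = incomplete$scenario$p,
               seed = incomplete$scenario$seed,
               allocation = incomplete$allocation)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
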