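#' Generate a synthetic cohort from a group profile
#'
#' Builds a complete cohort data frame whose per-outcome-group categorical
#' distributions follow `profile`. Two modes are available:
#'
#' * `"exact"`: every per-group marginal count is reproduced exactly.
#'   Within each outcome group, each variable's category values are laid out
#'   to the printed counts and assigned to records by an independent seeded
#'   permutation, so variables are independent given the outcome.
#' * `"stochastic"`: records are sampled per group from the profile
#'   proportions, optionally tilted by pairwise log-odds couplings
#'   (`dependence`) so that predictors carry within-group information about
#'   each other — without any such coupling (and beyond the outcome itself)
#'   model-based imputers have nothing to learn.
#'
#' @param profile A `group_profile`, e.g. [published_profile()].
#' @param mode `"exact"` or `"stochastic"`.
#' @param n Total cohort size for stochastic mode (group sizes allocated
#'   proportionally to the profile, failure count rounded). Ignored in exact
#'   mode, where the profile fixes n.
#' @param dependence Optional list of couplings for stochastic mode. Each
#'   element is `list(a, b, strength)`: both `a` and `b` must be two-level
#'   variables; when `a` takes its second-listed category, the log-odds of
#'   `b`'s second-listed category are shifted by `strength` within each
#'   outcome group. `a` is sampled from its marginal first.
#' @param seed Integer seed; the cohort is a deterministic function of
#'   `(profile, mode, n, dependence, seed)`.
#' @return A data frame of class `cohort`: one factor column per clinical
#'   variable plus integer `discharge_failure` (failure = 1), with
#'   attributes `mode` and `seed`. No missing values.
#' @export
#' @examples
#' coh <- generate_cohort(published_profile(), mode = "exact", seed = 1)
#' table(coh$deep_coma, coh$discharge_failure)
generate_cohort <- function(profile, mode = c("exact", "stochastic"),
                            n = NULL, dependence = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (!inherits(profile, "group_profile"))
    profile <- new_group_profile(profile$success_n, profile$failure_n,
                                 profile$counts)
  if (!is.null(dependence)) {
    for (cp in dependence) {
      if (length(cp) != 3)
        stop("each dependence entry must be list(a, b, strength)")
      if (!is.finite(cp[[3]])) stop("coupling strength must be finite")
    }
  }
  vars <- names(profile$counts)
  restore <- local_rng(seed)
  on.exit(restore())

  gen_group <- function(group, ng) {
    cols <- list()
    if (mode == "exact") {
      for (v in vars) {
        cnt <- profile$counts[[v]][[group]]
        vals <- rep(names(cnt), times = cnt)
        cols[[v]] <- vals[sample.int(ng)]
      }
    } else {
      coupled_b <- unique(vapply(dependence, function(cp) cp[[2]], ""))
      for (v in vars) {
        if (v %in% coupled_b) next     # sampled after its drivers below
        pr <- profile_proportions(profile, v, group)
        cols[[v]] <- sample(names(pr), ng, replace = TRUE, prob = pr)
      }
      for (b in coupled_b) {
        lev_b <- names(profile$counts[[b]][[group]])
        if (length(lev_b) != 2)
          stop("couplings are defined for two-level variables only")
        pr_b <- profile_proportions(profile, b, group)
        eta <- rep(stats::qlogis(min(max(pr_b[2], 1e-12), 1 - 1e-12)), ng)
        for (cp in dependence) {
          if (cp[[2]] != b) next
          a <- cp[[1]]
          lev_a <- names(profile$counts[[a]][[group]])
          if (length(lev_a) != 2)
            stop("couplings are defined for two-level variables only")
          if (is.null(cols[[a]]))
            stop("coupling driver '", a, "' may not itself be coupled")
          eta <- eta + ifelse(cols[[a]] == lev_a[2], cp[[3]], 0)
        }
        cols[[b]] <- ifelse(stats::runif(ng) < stats::plogis(eta),
                            lev_b[2], lev_b[1])
      }
      cols <- cols[vars]
    }
    cols
  }

  if (mode == "exact") {
    n_s <- profile$success_n; n_f <- profile$failure_n
  } else {
    if (is.null(n)) n <- profile$success_n + profile$failure_n
    n_f <- as.integer(round(n * profile$failure_n /
                              (profile$success_n + profile$failure_n)))
    n_f <- max(1L, min(n - 1L, n_f))
    n_s <- as.integer(n) - n_f
  }

  s_cols <- gen_group("success", n_s)
  f_cols <- gen_group("failure", n_f)
  df <- as.data.frame(
    c(lapply(vars, function(v)
        factor(c(s_cols[[v]], f_cols[[v]]),
               levels = names(profile$counts[[v]]$success))),
      list(c(rep(0L, n_s), rep(1L, n_f)))),
    col.names = c(vars, outcome_variable())
  )
  names(df) <- c(vars, outcome_variable())
  # interleave groups by a seeded permutation so row order carries no signal
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, mode = mode, seed = as.integer(seed),
            class = c("cohort", "data.frame"))
}

#' Validate a cohort data frame
#'
#' Checks that every clinical variable holds only legal categories, that the
#' outcome is 0/1, and (unless `allow_missing`) that no entry is missing.
#'
#' @param cohort A data frame with the cohort columns.
#' @param allow_missing Allow `NA` in the target variable only.
#' @return The cohort, invisibly; errors on violation.
#' @export
validate_cohort <- function(cohort, allow_missing = FALSE) {
  vars <- cohort_variables()
  miss_cols <- setdiff(c(names(vars), outcome_variable()), names(cohort))
  if (length(miss_cols))
    stop("cohort is missing columns: ", paste(miss_cols, collapse = ", "))
  for (v in names(vars)) {
    x <- cohort[[v]]
    bad <- !is.na(x) & !(as.character(x) %in% vars[[v]])
    if (any(bad))
      stop("illegal category in '", v, "': ",
           paste(unique(as.character(x)[bad]), collapse = ", "))
    if (any(is.na(x)) && !(allow_missing && v == target_variable()))
      stop("missing values in '", v, "' are not allowed here")
  }
  y <- cohort[[outcome_variable()]]
  if (any(is.na(y)) || !all(y %in% c(0L, 1L)))
    stop("outcome must be 0/1 with no missing values")
  invisible(cohort)
}

# run code under a private RNG stream; returns a restore function
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}
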