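#' Clinical variable registry for the stroke-discharge cohort
#'
#' The cohort carries eight categorical clinical variables recorded for
#' patients with spontaneous supratentorial intracerebral hemorrhage, plus a
#' binary discharge outcome (`discharge_failure`: failure = 1, success = 0).
#' Category order is fixed; the first-listed category is the reference level
#' and the deterministic tie-break everywhere in the package.
#'
#' @return Named list mapping each variable name to its ordered character
#'   vector of legal categories. The outcome variable is not included; it is
#'   always the 0/1 column `discharge_failure`.
#' @export
#' @examples
#' names(cohort_variables())
#' cohort_variables()$volume_ge30ml
cohort_variables <- function() {
  list(
    age            = c("<55", "55-64", "65-74", "75-84", ">84"),
    gender         = c("male", "female"),
    readmission_gt2 = c("no", "yes"),
    deep_coma      = c("no", "yes"),
    location       = c("deep", "superficial"),
    volume_ge30ml  = c("<30ml", ">=30ml"),
    operation      = c("no", "yes"),
    co_infection   = c("no", "yes")
  )
}

#' Name of the amputation/imputation target variable
#'
#' Supratentorial hemorrhage volume, dichotomized at 30 ml, is the variable
#' that goes missing in every simulated scenario: it is the clinically
#' important quantity most often unrecorded in practice.
#'
#' @return Character scalar `"volume_ge30ml"`.
#' @export
target_variable <- function() "volume_ge30ml"

#' Name of the binary outcome column
#' @return Character scalar `"discharge_failure"`.
#' @export
outcome_variable <- function() "discharge_failure"

#' Published group-wise count profile of the study cohort
#'
#' Returns the canonical `group_profile`: per-outcome-group category counts
#' for the eight clinical variables in a cohort of 1468 patients
#' (1207 discharge successes, 261 failures). These are the printed group-wise
#' marginals of the source cohort; the joint distribution is not published,
#' so generators built on this profile assume conditional independence of
#' the predictors given the outcome unless couplings are requested.
#'
#' @return An object of class `group_profile`: a list with `success_n`,
#'   `failure_n`, and `counts`, where `counts[[variable]]` is a list with
#'   integer vectors `success` and `failure` named by category.
#' @export
#' @examples
#' prof <- published_profile()
#' prof$counts$deep_coma$failure
published_profile <- function() {
  counts <- list(
    age = list(
      success = c("<55" = 249L, "55-64" = 265L, "65-74" = 391L,
                  "75-84" = 246L, ">84" = 56L),
      failure = c("<55" = 37L, "55-64" = 51L, "65-74" = 86L,
                  "75-84" = 60L, ">84" = 27L)
    ),
    gender = list(
      success = c(male = 688L, female = 519L),
      failure = c(male = 163L, female = 98L)
    ),
    readmission_gt2 = list(
      success = c(no = 1194L, yes = 13L),
      failure = c(no = 251L, yes = 10L)
    ),
    deep_coma = list(
      success = c(no = 1190L, yes = 17L),
      failure = c(no = 130L, yes = 131L)
    ),
    location = list(
      success = c(deep = 1081L, superficial = 126L),
      failure = c(deep = 220L, superficial = 41L)
    ),
    volume_ge30ml = list(
      success = c("<30ml" = 1032L, ">=30ml" = 175L),
      failure = c("<30ml" = 128L, ">=30ml" = 133L)
    ),
    operation = list(
      success = c(no = 1045L, yes = 162L),
      failure = c(no = 203L, yes = 58L)
    ),
    co_infection = list(
      success = c(no = 802L, yes = 405L),
      failure = c(no = 138L, yes = 123L)
    )
  )
  new_group_profile(success_n = 1207L, failure_n = 261L, counts = counts)
}

#' Construct and validate a group profile
#'
#' @param success_n,failure_n Group sizes (discharge success / failure).
#' @param counts Named list, one entry per variable, each a list with
#'   integer count vectors `success` and `failure` named by category.
#' @return A validated `group_profile` object.
#' @export
new_group_profile <- function(success_n, failure_n, counts) {
  stopifnot(is.numeric(success_n), is.numeric(failure_n),
            success_n > 0, failure_n > 0, is.list(counts), length(counts) > 0)
  for (v in names(counts)) {
    cv <- counts[[v]]
    if (!all(c("success", "failure") %in% names(cv)))
      stop("profile variable '", v, "' must have success and failure counts")
    if (!identical(names(cv$success), names(cv$failure)))
      stop("category labels differ between groups for '", v, "'")
    if (sum(cv$success) != success_n)
      stop("success counts for '", v, "' sum to ", sum(cv$success),
           ", expected ", success_n)
    if (sum(cv$failure) != failure_n)
      stop("failure counts for '", v, "' sum to ", sum(cv$failure),
           ", expected ", failure_n)
    if (any(cv$success < 0) || any(cv$failure < 0))
      stop("negative count in profile variable '", v, "'")
  }
  structure(list(success_n = as.integer(success_n),
                 failure_n = as.integer(failure_n),
                 counts = counts),
            class = "group_profile")
}

#' @export
print.group_profile <- function(x, ...) {
  cat("<group_profile> n =", x$success_n + x$failure_n,
      "(success", x$success_n, "/ failure", x$failure_n, ")\n")
  cat("variables:", paste(names(x$counts), collapse = ", "), "\n")
  invisible(x)
}

# proportions of each category within a group, for stochastic sampling
profile_proportions <- function(profile, variable, group) {
  cnt <- profile$counts[[variable]][[group]]
  cnt / sum(cnt)
}
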