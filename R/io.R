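#' Read and write cohort CSV files
#'
#' The on-disk dialect is a plain UTF-8 CSV with header
#' `age,gender,readmission_gt2,deep_coma,location,volume_ge30ml,operation,
#' co_infection,discharge_failure`, categories as literal strings, one record
#' per row, and missing values as empty fields (only legal in the target
#' column). The round-trip is lossless including missingness.
#'
#' @param cohort A cohort data frame (NA allowed in the target variable).
#' @param path File path.
#' @return `read_cohort` returns a validated cohort data frame;
#'   `write_cohort` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort, allow_missing = TRUE)
  out <- cohort[c(names(cohort_variables()), outcome_variable())]
  out[] <- lapply(out, as.character)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = "", check.names = FALSE)
  vars <- cohort_variables()
  expected <- c(names(vars), outcome_variable())
  if (!identical(names(raw), expected))
    stop("malformed cohort file: header must be ",
         paste(expected, collapse = ","))
  df <- raw
  for (v in names(vars)) {
    bad <- !is.na(raw[[v]]) & !(raw[[v]] %in% vars[[v]])
    if (any(bad))
      stop("unknown category in '", v, "': ",
           paste(unique(raw[[v]][bad]), collapse = ", "))
    df[[v]] <- factor(raw[[v]], levels = vars[[v]])
  }
  df[[outcome_variable()]] <- as.integer(raw[[outcome_variable()]])
  validate_cohort(df, allow_missing = TRUE)
  structure(df, class = c("cohort", "data.frame"))
}
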