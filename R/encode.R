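#' Encode a cohort as a numeric feature matrix
#'
#' Two schemes are supported, matching the conventions of the model families
#' that consume them:
#'
#' * `"onehot"`: two-level variables become a single 0/1 indicator of the
#'   second-listed category; age (5 levels) becomes five indicator columns.
#'   Used (with unit-variance scaling downstream) by distance- and
#'   margin-based methods (KNN, logistic regression, neural net, SVM).
#' * `"ordinal"`: every variable becomes its integer category code
#'   (0-based), treating age as ordered. Used by tree ensembles, keeping the
#'   design at 8 unexpanded predictors (7 covariates + outcome).
#'
#' The outcome column is always included as a plain 0/1 column; imputation
#' models use it as a predictor of the missing clinical variable. The
#' encoding of the target variable is a single column in both schemes, so it
#' is invertible via [decode_target()].
#'
#' @param cohort A cohort data frame (missing values allowed in the target).
#' @param scheme `"onehot"` or `"ordinal"`.
#' @return An object of class `feature_matrix`: list with the numeric
#'   `matrix`, the `scheme`, and per-column metadata `columns`
#'   (source variable and category represented).
#' @export
encode_features <- function(cohort, scheme = c("onehot", "ordinal")) {
  scheme <- match.arg(scheme)
  vars <- cohort_variables()
  cols <- list(); meta_var <- character(); meta_cat <- character()
  for (v in names(vars)) {
    levs <- vars[[v]]
    x <- factor(as.character(cohort[[v]]), levels = levs)
    if (any(!is.na(cohort[[v]]) & is.na(x)))
      stop("unseen category in '", v, "'")
    if (scheme == "ordinal" || length(levs) == 2) {
      code <- as.integer(x) - 1L
      cols[[length(cols) + 1L]] <- code
      meta_var <- c(meta_var, v)
      meta_cat <- c(meta_cat, if (length(levs) == 2) levs[2] else "ordinal")
      names(cols)[length(cols)] <- v
    } else {
      for (lv in levs) {
        cols[[length(cols) + 1L]] <- as.integer(x == lv)
        meta_var <- c(meta_var, v)
        meta_cat <- c(meta_cat, lv)
        names(cols)[length(cols)] <- paste0(v, ".", lv)
      }
    }
  }
  cols[[length(cols) + 1L]] <- as.integer(cohort[[outcome_variable()]])
  names(cols)[length(cols)] <- outcome_variable()
  meta_var <- c(meta_var, outcome_variable())
  meta_cat <- c(meta_cat, "1")
  m <- do.call(cbind, cols)
  structure(list(matrix = m, scheme = scheme,
                 columns = data.frame(column = colnames(m),
                                      variable = meta_var,
                                      category = meta_cat,
                                      stringsAsFactors = FALSE)),
            class = "feature_matrix")
}

#' Decode the target-variable column of a feature matrix
#'
#' @param fm A `feature_matrix` from [encode_features()].
#' @param codes Optional numeric vector of 0/1 codes to decode instead of
#'   the matrix column.
#' @return Factor of target categories (`NA` preserved).
#' @export
decode_target <- function(fm, codes = NULL) {
  levs <- cohort_variables()[[target_variable()]]
  if (is.null(codes)) codes <- fm$matrix[, target_variable()]
  factor(ifelse(is.na(codes), NA_character_,
                ifelse(codes >= 0.5, levs[2], levs[1])),
         levels = levs)
}

# design matrix of predictors for target-variable imputation models:
# everything except the target, per-scheme encoding, optional unit-variance
# scaling (constant columns left untouched). drop_first switches multi-level
# one-hot blocks to treatment coding (reference level dropped) for
# intercept-bearing regression fits, where the full block is collinear.
build_design <- function(cohort, scheme, scale = (scheme == "onehot"),
                         drop_first = FALSE) {
  fm <- encode_features(cohort, scheme)
  keep <- fm$columns$variable != target_variable()
  if (drop_first && scheme == "onehot") {
    vars <- cohort_variables()
    multi <- names(vars)[vapply(vars, length, 0L) > 2]
    ref_cols <- paste0(multi, ".", vapply(vars[multi], `[`, "", 1L))
    keep <- keep & !(fm$columns$column %in% ref_cols)
  }
  X <- fm$matrix[, keep, drop = FALSE]
  if (scale) {
    s <- apply(X, 2, stats::sd)
    s[!is.finite(s) | s == 0] <- 1
    X <- sweep(X, 2, s, "/")
  }
  X
}
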