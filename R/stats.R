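#' Exact one-sided Wilcoxon signed-rank test
#'
#' Paired test of whether `x` tends to exceed `y`. Zero differences are
#' dropped (classical reduced-sample practice); ties in |difference| get
#' midranks; the p value is exact — the proportion of all 2^n sign
#' assignments of the (possibly tied) rank configuration whose
#' positive-rank sum is at least the observed one, computed by dynamic
#' programming over the doubled (integer) midranks. With all differences
#' zero the p value is 1 by convention.
#'
#' Designed for the short paired series that arise when two methods are
#' compared across a proportion grid (n of 6 canonically; exact up to
#' n = 30 comfortably).
#'
#' @param x,y Numeric vectors of equal length (e.g. one metric for two
#'   methods across the proportion grid, aligned).
#' @return The exact one-sided p value.
#' @export
#' @examples
#' wilcoxon_exact_one_sided(c(2, 3, 4, 5, 6, 7), rep(1, 6))  # 1/64
wilcoxon_exact_one_sided <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))              # midranks under ties
  w <- as.integer(round(2 * r))  # doubled ranks are integers
  w_obs <- sum(w[d > 0])
  total <- sum(w)
  counts <- numeric(total + 1L)  # counts[s + 1] = #assignments with sum s
  counts[1L] <- 1
  for (wi in w) {
    shifted <- c(numeric(wi), counts[seq_len(total + 1L - wi)])
    counts <- counts + shifted
  }
  sum(counts[(w_obs + 1L):(total + 1L)]) / 2^n
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment of a family of p values (wraps
#' `stats::p.adjust(method = "BH")`): sorted ascending,
#' p~(i) = min over j >= i of p(j) * m / j, capped at 1, returned in the
#' input order.
#'
#' @param pvals Numeric vector of raw p values in (0, 1\].
#' @return Adjusted p values, same order and length.
#' @export
#' @examples
#' bh_adjust(c(0.016, 0.016, 0.016, 0.018, 0.016, 0.016, 0.016))
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector")
  stopifnot(all(pvals > 0), all(pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Compare the ensemble against every other method
#'
#' For each evaluation metric within each missing mechanism, runs the seven
#' paired one-sided exact Wilcoxon signed-rank tests of the ensemble (EL)
#' against each other method across the proportion grid, and adjusts the
#' seven p values jointly by Benjamini-Hochberg within that
#' metric-by-mechanism family. The alternative is that EL's metric values
#' tend to exceed the comparator's.
#'
#' @param results Long-format results data frame with columns `mechanism`,
#'   `proportion`, `method`, `sensitivity`, `auc`, `kappa` (one row per
#'   scenario x method), e.g. `run_experiment()$results`.
#' @param el Identifier of the ensemble column (default `"EL"`).
#' @param alpha Significance level for the flag (default 0.05).
#' @return Data frame: `mechanism`, `metric`, `comparison`, `p_raw`,
#'   `p_adj`, `significant`.
#' @export
compare_el <- function(results, el = "EL", alpha = 0.05) {
  metrics <- c("sensitivity", "auc", "kappa")
  stopifnot(all(c("mechanism", "proportion", "method", metrics)
                %in% names(results)))
  if (!el %in% results$method)
    stop("results contain no '", el, "' method column")
  others <- setdiff(unique(results$method), el)
  out <- list()
  for (mech in unique(results$mechanism)) {
    sub <- results[results$mechanism == mech, , drop = FALSE]
    sub <- sub[order(sub$proportion), , drop = FALSE]
    el_rows <- sub[sub$method == el, , drop = FALSE]
    for (metric in metrics) {
      p_raw <- vapply(others, function(m) {
        cmp <- sub[sub$method == m, , drop = FALSE]
        if (nrow(cmp) != nrow(el_rows))
          stop("misaligned series for method '", m, "'")
        wilcoxon_exact_one_sided(el_rows[[metric]], cmp[[metric]])
      }, numeric(1))
      p_adj <- bh_adjust(p_raw)
      out[[length(out) + 1L]] <- data.frame(
        mechanism = mech, metric = metric,
        comparison = paste0(el, " vs ", others),
        p_raw = p_raw, p_adj = p_adj,
        significant = p_adj < alpha,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
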