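# imputeImpact

**Decision-impact benchmarking of missing-data imputation methods for
clinical prediction.**

Most imputation benchmarks score a method by how well it recovers the true
values or their distribution. For clinical decision making that criterion is
often beside the point: what matters is whether the *decisions* made by a
model fitted to the imputed data change. `imputeImpact` implements that
evaluation end to end for the motivating application — discharge assessment
of patients with spontaneous supratentorial intracerebral hemorrhage, where
the hemorrhage-volume variable (dichotomized at 30 ml) is the one most often
missing.

The pipeline:

1. **Synthesize a cohort** of n = 1468 patients (1207 discharge successes,
   261 failures) across eight categorical clinical variables from published
   group-wise counts (`published_profile()`, `generate_cohort()`), either
   reproducing every per-group marginal exactly or sampling stochastically
   with configurable within-group dependence.
2. **Ampute** the volume variable under MCAR and two outcome-dependent MAR
   mechanisms (group missing-proportion ratios 1:2 and 2:1) at proportions
   5–50% — the canonical 3 × 6 = 18 scenarios (`ampute()`,
   `enumerate_scenarios()`).
3. **Impute** with eight methods (`impute_with()`): mode, k-nearest
   neighbours (k = 10, median of donors), MICE with predictive mean matching
   (m = 20 × 50 iterations), and grid-search-tuned logistic regression,
   random forest, neural network, RBF-SVM, and a stacked-generalization
   ensemble of the four with an RBF-SVM meta-learner.
4. **Evaluate** each completed cohort by the discharge logistic model's
   sensitivity `TP/(TP+FN)`, rank-based AUC, and Cohen's kappa
   `(p_o − p_e)/(1 − p_e)` against the complete-data reference
   (`evaluate_scenario()`, `compute_metrics()`).
5. **Test** whether the ensemble's advantage is significant with exact
   one-sided Wilcoxon signed-rank tests paired over the proportion grid and
   Benjamini–Hochberg FDR adjustment (`wilcoxon_exact_one_sided()`,
   `compare_el()`).

`run_experiment()` drives the whole design deterministically from one seed;
`write_report()` emits long/wide CSV tables and a provenance manifest. See
`vignettes/decision-impact-imputation.Rmd` for the methods account.

## Worked example

```r
library(imputeImpact)

coh <- generate_cohort(published_profile(), mode = "exact", seed = 1)
table(coh$volume_ge30ml, coh$discharge_failure)
#>             0    1
#>   <30ml  1032  128
#>   >=30ml  175  133

inc <- ampute(coh, missing_scenario("MAR_2_1", 0.30, seed = 1))
inc
#> <incomplete_cohort> n=1468 missing=440 (MAR_2_1 p=0.3)

cfg  <- imputer_config(fast = TRUE, seed = 1)
comp <- impute_with(inc, "EL", cfg)
comp
#> <completed_cohort> n=1468 method=EL imputed=440 cells

ref <- evaluate_scenario(coh)$metrics          # complete-data reference
ref
#> sensitivity 0.521 | AUC 0.873 | kappa 0.599 (threshold 0.5)

evaluate_scenario(comp, reference = ref)$metrics
#> sensitivity 0.502 | AUC 0.831 | kappa 0.585 (threshold 0.5)
```

The cross-tabulation reproduces the published volume-by-outcome counts
exactly (133 of 261 failures with volume ≥ 30 ml). Amputing 30% of volume
values under MAR 2:1 blanks 440 cells (133 failure / 307 success — a
realized group-proportion ratio of 2.003). After ensemble imputation the
refitted discharge model loses a little sensitivity and AUC relative to the
complete-data reference; that loss, accumulated over all 18 scenarios and 8
methods, is exactly what the benchmark quantifies. Note the exact-mode
cohort is conditionally independent given the outcome, so absolute metric
values differ from any particular real cohort; relative method behaviour is
the object of study.

Exact small-sample inference, e.g. the ensemble dominating a comparator at
all six proportions:

```r
wilcoxon_exact_one_sided(2:7, rep(1, 6))
#> [1] 0.015625        # = 1/64, the exact floor for n = 6
```

## Command line

A thin wrapper over the same functions lives at
`inst/scripts/run_experiment.R`:

```sh
Rscript inst/scripts/run_experiment.R generate --outdir out --seed 1
Rscript inst/scripts/run_experiment.R run --config cfg.yaml --outdir out --fast
Rscript inst/scripts/run_experiment.R report --results out/results.csv --outdir out
```
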