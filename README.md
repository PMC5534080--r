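# survforests

Survival trees and forests for right-censored time-to-event data, built from
first principles to study one question: **when covariates differ in their
number of split points, which forest model should you trust?**

Classification-style recursive partitioning greedily maximizes a split
statistic over every candidate cut of every candidate covariate. A covariate
with many admissible splits (a polytomous factor with many levels) gets more
chances to produce a spuriously large statistic than a binary one, so greedy
survival trees — and the random survival forests (RSF) built from them — are
biased towards many-split-point covariates. Conditional inference forests
(CIF) remove that bias by separating the two decisions: first a
permutation-framework association test selects the covariate (every covariate
gets exactly one test, whatever its cardinality), then the split point is
searched on the selected covariate only.

The package implements all three competitors and the machinery to compare
them:

- **RSF1** — random survival forest, trees grown with the two-sample
  **log-rank** split statistic (observed − expected events over pooled event
  times, standardized by the hypergeometric variance).
- **RSF2** — random survival forest with the **log-rank-score** rule: each
  subject gets a rank score
  `a_l = δ_l − Σ_{k≤l} δ_k / (N − k + 1)`
  and a split is rated by
  `|Σ_left a_j − R₁ ā| / sqrt(R₁ (1 − R₁/N) S_a²)`.
- **CIF** — conditional inference forest: per-node linear rank tests of each
  covariate against the node's log-rank scores (quadratic-form statistic,
  χ² reference, Monte-Carlo permutation option), Bonferroni min-p variable
  selection, then a standard binary split search; prediction by a
  terminal-size-weighted Kaplan–Meier over the training set.
- A **Weibull proportional-hazards simulation engine** with per-design
  censoring rates calibrated by Monte-Carlo root finding, including a
  22-design registry spanning binary, polytomous, mixed and interaction
  covariate regimes.
- **IPCW Brier score** curves `BS(t)`, the normalized **integrated Brier
  score** (IBS), and the **.632+ bootstrap** cross-validated prediction error
  — the single currency in which the models are compared (prediction errors
  of 50% or more are no better than a coin toss).

The tree-growing core is compiled (Rcpp), so full benchmark sweeps run in
minutes on a laptop.

## Worked example

```r
library(survforests)

design <- get_design("binary2")      # n=100, 50% censoring, decreasing hazard
dat <- gen_dataset(design, seed = 42)
print(dat)
#> Right-censored survival dataset: 100 subjects, 10 covariates
#>   events: 52 (48.0% censored)
#>   design: binary2

reports <- boot632plus(standard_models(n_trees = 100), dat, B = 5, seed = 42)
cat(reports$rsf1$ibs632, reports$rsf2$ibs632, reports$cif$ibs632, "\n")
#> 0.2151587 0.2136564 0.2185313
```

Each number is a .632+ bootstrap cross-validated integrated Brier score: the
time-averaged squared error of the predicted survival probabilities, weighted
for censoring, on a 0–1 scale where 0 is perfect, 0.25 is a constant 50/50
guess and anything at or above 0.5 is useless. At n = 100 with ~50%
censoring all three forests sit well below the bound and within noise of one
another — exactly the "comparable on binary covariates" regime; the
separation appears on the polytomous designs below.

The full simulation comparison (any subset of the 22 designs, repeated with
fresh data and per-cell reproducible seeds) is one call:

```r
res <- benchmark_repetitions(as.list(paste0("poly", 1:6)),
                             standard_models(n_trees = 100),
                             n_reps = 10, B = 5, seed = 2026)
plot_benchmark(res)   # box plots of IBS by model, per design
```

On the polytomous (many-split-point) designs CIF attains the lowest median
IBS in five of the six designs; on the binary designs the three models'
interquartile ranges overlap throughout — the cardinality of the covariates,
not the overall signal, is what separates the models.

A thin CLI covers the two common entry points
(`inst/cli/survforest.R simulate ...` and `... benchmark --config run.yaml`).

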