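---
title: "Comparing random and conditional inference survival forests"
author: "survforests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing random and conditional inference survival forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(survforests)
```

## The problem

Right-censored time-to-event data pair an observed follow-up time $T_i$ with
an event indicator $\delta_i$ ($1$ = event, $0$ = censored) and a covariate
vector $x_i$. Survival trees partition the covariate space into groups with
homogeneous survival experience; forests of such trees give flexible,
assumption-light survival predictions. But the greedy split search that makes
trees work also biases them: a covariate offering many candidate splits (an
unordered factor with $L$ levels offers $2^{L-1}-1$) produces, by chance
alone, larger maximal split statistics than a binary covariate. Random
survival forests inherit this preference for many-split-point covariates;
conditional inference forests were designed to remove it. This package
implements both families and a simulation-plus-evaluation pipeline to
measure, under controlled covariate regimes, when the difference matters.

## The three models

All trees are binary recursive partitions. Numeric covariates split as
$x \le c$ over midpoints of observed values; factors split by exhaustive
search over proper level subsets (refused above 8 levels — exactness over
heuristics at the scale studied here). A split is admissible only if both
children meet the minimum node size and minimum event count. Ties between
equal-statistic splits go to the lowest covariate index, then the smallest
split set in canonical order, making every fit replayable.

**RSF1 (log-rank rule).** At each node, `mtry` candidate covariates are drawn
without replacement and the standardized two-sample log-rank statistic

$$ Z = \frac{\sum_t \left(d_{1t} - d_t\,n_{1t}/n_t\right)}
{\sqrt{\sum_t d_t \frac{n_{1t}}{n_t}\left(1-\frac{n_{1t}}{n_t}\right)
\frac{n_t-d_t}{n_t-1}}} $$

is maximized in absolute value over all admissible splits ($d_t$, $n_t$:
deaths and at-risk at pooled event time $t$; subscript 1: left child).

**RSF2 (log-rank-score rule).** Each node subject receives a rank score
$a_l = \delta_l - \sum_{k=1}^{l} \delta_k/(N-k+1)$ computed over the node's
time ordering (events precede censorings at tied times; for uncensored
distinct times the scores telescope to sum 0). The split statistic is
$|i(x, s)| = |\sum_{\text{left}} a_j - R_1\bar a| / \sqrt{R_1(1-R_1/N)S_a^2}$
with $\bar a$, $S_a^2$ the node's score mean and sample variance and $R_1$
the left-child size.

Both RSFs grow each tree on an independent bootstrap sample (size $N$, with
replacement; all node counts respect bootstrap multiplicity). Ensemble
prediction averages terminal-node Nelson–Aalen cumulative hazards across
trees with equal weights and converts to survival, so predicted curves are
automatically proper (in $[0,1]$, non-increasing, starting at 1).

**CIF.** Variable selection is separated from split search. At each node the
log-rank scores $a$ are recomputed for the node's subjects, and each
candidate covariate is tested for association with $a$ in the permutation
framework: the vector of per-level score sums is centred by its exact
conditional mean and standardized by its exact conditional covariance
$\hat\sigma^2_a(\mathrm{diag}(n_l) - n\,n^\top/N)$, then summarized as a
quadratic form with a $\chi^2_{L-1}$ reference distribution. A numeric
covariate enters linearly through its own values (a single-df linear rank
statistic) rather than as a high-cardinality factor. The minimum
Bonferroni-adjusted p-value selects the covariate; if it exceeds `alpha` the
node becomes terminal. The split point on the selected covariate then
maximizes the same standardized score statistic as RSF2, restricted to that
one covariate. CIF trees are grown on subsamples drawn *without* replacement
(fraction 0.632), and prediction is the weighted Kaplan–Meier over the whole
training set, with weights accumulated across trees as (co-membership in the
new subject's terminal) / (terminal in-bag size) — terminals with many
subjects at risk therefore carry more weight, and with a single root-only
tree the prediction reduces exactly to the ordinary Kaplan–Meier.

### Why a quadratic-form test statistic

The association test could standardize each level contrast separately and
take the maximum absolute component, with a multivariate-normal reference.
We use the quadratic form instead: for binary covariates the two are
identical ($z^2$ vs $|z|$), it needs no multivariate-normal quadrature, and —
decisive for the bias question — its $\chi^2_{L-1}$ p-values are equally
calibrated whatever the level count, so min-p selection cannot smuggle the
cardinality bias back in. A Bonferroni bound over components, by contrast,
would be increasingly conservative with more levels and bias selection
*against* polytomous covariates. At nodes smaller than `small_n` the
asymptotic reference is replaced by a seeded Monte-Carlo permutation p-value
(default 9999 draws); selection uses raw p-values (the Bonferroni adjustment
only gates stopping) because capped adjusted values would tie at 1 and fall
back to column order.

### Single-tree vs ensemble defaults

`grow_ctree()` uses the classic early-stopping single-tree convention:
`alpha = 0.05`, Bonferroni, node minimum 15 subjects / 3 events per child,
Monte-Carlo p-values below 30 subjects. `fit_cif()` deliberately follows the
*forest* convention of the reference conditional-inference implementation
instead: `alpha = 1` (no p-value stopping — the association test still picks
the variable, but tree size is controlled by the node limits), `mtry = 5`,
children of at least 7 subjects and 1 event, asymptotic p-values throughout.
The difference matters: with early stopping on 0.632-subsamples CIF trees
average a third the terminals of the corresponding RSF trees and visibly
underfit — on a polytomous design their RMSE against the true conditional
survival curves was 0.29 vs 0.25 for RSF, inverting the comparison the
ensembles are meant to make. With the forest convention CIF reaches 0.247 on
the same check. RSF trees use `mtry = ceiling(sqrt(p))` and the common
survival-forest node minimum of 15 subjects with at least 3 events per
child.

## The simulation engine

Event times follow a Weibull proportional-hazards model with baseline hazard
$h_0(t) = (\theta/\rho^\theta)\,t^{\theta-1}$. Writing
$\beta_0 = \log \rho^{-\theta}$, each subject's Weibull *scale* is
$\lambda_i = \exp(-\beta_0/\theta - \textstyle\sum_j \beta_j x_{ij}/\theta)$
and times are drawn by inverting the cumulative hazard,
$T_i = \lambda_i(-\log U)^{1/\theta}$, so the cumulative hazard is
$t^\theta e^{\beta_0 + \sum\beta_j x_{ij}}$, each $\beta_j$ is a log hazard
ratio, and $\theta > 1$, $< 1$, $= 1$ give increasing, decreasing and
constant hazards ($\theta = 1$: exponential with mean $\lambda$). Censoring
times are Weibull with a fixed shape and a scale calibrated by bisection on
$\log(\text{scale})$ against a dedicated 10,000-subject probe sample with
common random numbers (tolerance 0.02 censoring fraction; a target of 0
yields an infinite scale, i.e. no censoring). The probe seed is fixed, so a
design's calibrated scale is a deterministic property of the design, and
datasets are bit-reproducible from their seed.

The built-in registry holds 22 designs in four families (sample sizes 100 to
2000, censoring targets 20/50/80%):

- **binary1–6**: ten Bernoulli(0.5) covariates. The decreasing-hazard
  designs use $\theta = 0.8$, $\beta_0 = -0.98$, censoring shape 0.4 and
  coefficients {0.5, −0.045, 0.6, −0.03, −2, 0.5, 0.25, −0.04, 0.33, 0.3};
  the increasing-hazard designs $\theta = 1.5$, $\beta_0 = -1.44$, censoring
  shape 2.4 and {0.1, −0.8, 0.5, −0.2, −3, 0.7, 0.2, 0.4, 0.3, 0} (the
  nine-value vector padded with a trailing 0); the constant-hazard designs
  $\theta = 1$, $\beta_0 = 0.9$, censoring shape 1 and
  {0.4, −0.7, 1, −2, −3, 0.7, 0.06, 0.5, −0.43, 0.3}. The Bernoulli
  probabilities are not separately specified per covariate; 0.5 is the
  package default and is overridable per `covariate_spec`.
- **poly1–6**: ten polytomous covariates with level counts cycling 3, 4, 5,
  equal sampling weights, per-level coefficients equally spaced on
  $[-1, 1]$; $\theta \in \{0.5, 1.5, 1\}$ for decreasing / increasing /
  constant hazard, censoring shapes 0.4 / 1.2 / 1.1 respectively,
  $\beta_0 = 0$.
- **mixed1–6**: five binary covariates (coefficients 0.5, −0.8, 1, −0.5,
  0.7) plus five polytomous covariates as above, same event model as the
  polytomous family.
- **interact1–4**: the mixed covariates plus two binary-by-polytomous
  product terms with coefficients +0.7 and −0.7; a binary covariate enters
  the product as its 0/1 value, a polytomous one as an equally spaced level
  score on $[-1, 1]$.

These choices emulate the covariate *regimes* of interest — many-level
categorical covariates under heavy censoring, binary-only covariates at
small $n$ — not any particular cohort's joint covariate distribution,
correlation structure, or non-Weibull censoring patterns. Passing tests on
these designs therefore demonstrates correct behaviour of the methods under
proportional hazards with independent covariates; it cannot certify
performance on real data with informative censoring or correlated
predictors.

## Evaluation

Prediction error is the inverse-probability-of-censoring-weighted Brier
score

$$ BS(t) = \frac{1}{N}\sum_l
\hat S(t|x_l)^2\,\frac{\mathbb 1(t_l \le t,\ \delta_l = 1)}{\hat G(t_l)}
+ (1-\hat S(t|x_l))^2\,\frac{\mathbb 1(t_l > t)}{\hat G(t)} $$

with $\hat G$ the Kaplan–Meier estimator of the censoring survival function
(event indicator reversed; at tied times censorings are taken to occur just
after events, the standard IPCW convention). Subjects censored before $t$
contribute nothing; with no censoring the formula reduces exactly to the
plain Brier score. The integrated Brier score is the trapezoidal integral of
$BS(t)$ divided by the grid span, so it is unitless in $[0,1]$ and
comparable across follow-up lengths: a constant prediction of 0.5 scores
0.25, and 0.5 is the coin-toss uselessness bound.

The evaluation grid is shared by all models and folds of one comparison: the
unique event times of the full dataset, truncated at the 95th percentile of
follow-up and wherever $\hat G > 0$ (keeping the $1/\hat G$ weights stable),
thinned to at most 64 quantile-spaced points. A shared grid is what makes
the apparent, bootstrap and no-information curves commensurable in the
.632+ combination; the 64-point cap changes the trapezoid integral
negligibly while bounding the cost of scoring 100-tree forests thousands of
times.

`boot632plus()` draws $B$ bootstrap samples (redrawing any whose out-of-bag
part has no events), refits every model on each in-bag set, scores it on the
out-of-bag subjects, and combines the pooled out-of-bag curve
$\widehat{err}^{(1)}$ with the apparent curve and the no-information curve
$\gamma$ (every prediction scored against every outcome — which factorizes,
so it costs $O(N)$ per grid point) via the relative overfitting rate
$R = (\widehat{err}^{(1)} - err_{app})/(\gamma - err_{app})$, clipped to
$[0,1]$ after capping $\widehat{err}^{(1)}$ at $\gamma$, and the weight
$w = 0.632/(1 - 0.368 R)$. The default is $B = 5$, matching the headline study conditions.
All models share the same bootstrap draws, the same $\hat G$ (estimated once
from the full data) and the same grid.

`benchmark_repetitions()` repeats the whole procedure over fresh datasets.
Per-cell seeds derive from the base seed, the design *id* (hashed, not the
list position) and the repetition index, so any subset of cells rerun in any
order reproduces identical rows.

## Numerical and degenerate-input choices

- Zero events in a node (or zero score variance) make the split statistics
  undefined; such splits are skipped, and the exported statistic functions
  signal a distinct `undefined_statistic` condition rather than returning 0.
- All-censored training data yield a root-only tree with a flat survival
  curve and a warning.
- Factor levels unseen at training time are routed to the child with more
  training subjects, with a warning; subjects out-of-bag in no tree get `NA`
  predictions, likewise flagged.
- Bisection for the censoring scale runs on $\log(\text{scale})$ with
  bracket expansion and common random numbers, so the empirical censoring
  fraction is monotone in the scale and the search cannot oscillate.
- Permutation importance uses the out-of-bag integrated Brier score as its
  loss — the same currency as the model comparison — so importances are
  directly interpretable as IBS increases under covariate scrambling.

## Scale of the shipped experiments

The package's replication experiment runs the six polytomous and six binary
designs at 10 repetitions, 100 trees and $B = 5$ (the tree count and $B$
match the headline study conditions; repetitions are scaled from 100 to 10,
which is ample for the median-ordering and IQR-overlap questions the
comparison asks). That sweep completes in roughly seven minutes on one CPU.
Calibration suites use 500–1000 Monte-Carlo replicates; design-recovery
checks use fresh samples of 10,000 subjects per design.

## Known limitations

- Unordered factors are limited to 8 levels (exhaustive subset search).
- The log-rank split rules assume proportional hazards within a node;
  crossing-hazards split rules are out of scope.
- No missing-data handling: complete cases only.
- The IBS depends (mildly) on the evaluation grid and truncation; absolute
  IBS levels are therefore comparable within a `boot632plus()` call, while
  orderings — the quantity of scientific interest here — are stable across
  grid choices.
- Variable importance is marginal permutation importance; conditional
  importance for correlated covariates is not implemented.
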