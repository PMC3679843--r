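---
title: "A k-nearest-neighbour applicability domain with per-sample thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A k-nearest-neighbour applicability domain with per-sample thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
library(applidom)
```

## The problem

A QSAR model interpolates: it is trustworthy only for query structures that
resemble its training set. The *applicability domain* (AD) is the region of
descriptor space where the model's predictions can be considered reliable.
Classical AD definitions use a single global rule — the descriptor ranges
(bounding box), the convex hull, a percentile of centroid distances, or a
single distance cutoff on average k-nearest-neighbour distances. All of these
struggle when the training data are unevenly dense, contain internal voids,
or include a few extreme outliers: a global rule is either too loose around
outliers or too tight around dense regions.

This package implements a kNN-based AD in which **every training sample
carries its own distance threshold**, so the domain adapts to the local
density of the training set. The procedure has three stages.

## The method

All distances are computed on autoscaled descriptors (training mean and
standard deviation; queries are scaled with the *training* statistics).
Quartiles use the standard linear-interpolation convention by default
(`quantile_rule = "linear"`, i.e. R's type 7); a nearest-rank alternative
(`"nearest"`, type 1) is available throughout.

**Stage 1 — a reference value.** For each training sample $i$, compute the
mean distance $\bar d_i(k)$ to its $k$ nearest training neighbours. The
*reference value* is the Tukey upper fence of these averages,

$$\mathrm{RefVal} = Q_3 + 1.5\,(Q_3 - Q_1),$$

the familiar box-plot whisker limit: any neighbourhood wider than what the
bulk of the training set exhibits is considered atypical.

**Stage 2 — per-sample thresholds.** Each training sample $i$ keeps only its
neighbours within RefVal. The count of kept neighbours is $K_i$ (a local
density measure) and the sample's own threshold is

$$t_i = \frac{1}{K_i} \sum_{j:\, D_{ij} \le \mathrm{RefVal}} D_{ij},$$

the mean of the retained distances. Samples with $K_i = 0$ — points so
isolated that not even their nearest neighbour is within RefVal — receive
the **fallback threshold**: the minimum $t_i$ over all non-isolated samples.
This deliberately gives outliers the *tightest* threshold in the model, so
an outlier in the training set does not open up a large spurious region of
domain around itself.

**Stage 3 — the decision rule.** A query $q$ is inside the AD iff it is
within at least one training sample's threshold:

$$q \in \mathrm{AD} \iff \exists\, i:\ d(q, x_i) \le t_i .$$

The number of thresholds satisfied, $K_q$, is returned alongside the binary
decision: it grades how deeply the query sits inside the domain and can be
read as a per-prediction reliability score.

```{r worked}
# a hand-checkable 1-D example: three points at 0, 1, 3 with k = 1
train <- descriptor_table(matrix(c(0, 1, 3), ncol = 1))
model <- fit_ad(train, k = 1, pretreat = FALSE)
model$t          # per-sample thresholds: 1, 1.5, 2
apply_ad(model, descriptor_table(matrix(2), ids = "q"))
```

## Choosing the smoothing parameter k

`k` controls how smooth the local density estimate is. The package offers
two choices:

* `default_k(n)` — the empirical cube-root rule $k = \lfloor n^{1/3}
  \rceil$, used when no `k` is supplied;
* `optimize_k()` — a Monte Carlo procedure: repeatedly hold out 20 % of the
  training samples, fit the AD on the rest for every `k` in a grid, and
  record the percentage of held-out samples retained in the domain. The
  per-`k` distributions are summarised as box plots; `suggest_k()` picks the
  smallest `k` on the plateau of the mean curve (within 2 % of the maximum)
  without box-plot outliers, i.e. the least smoothing that already covers
  the data stably.

```{r optk}
sim <- simulate_cluster_with_outliers(seed = 42)   # 48 cluster points + 2 outliers
opt <- optimize_k(sim, k_grid = 1:25, iterations = 200, seed = 1)
plot(opt)
suggest_k(opt)
```

### A caveat: monotonicity in k is a tendency, not a theorem

The average neighbour distances $\bar d_i(k)$ are provably non-decreasing in
$k$, and in the typical case RefVal, the thresholds and the domain grow with
$k$ as well. But the Tukey fence $2.5\,Q_3 - 1.5\,Q_1$ is **not** monotone
under elementwise-increasing inputs: if $Q_1$ grows faster than $Q_3$
between consecutive $k$, the fence — and everything downstream — can
briefly shrink. On random data this happens in well under 1 % of
consecutive-$k$ transitions, but it does happen (we observed, for example,
RefVal dropping from 1.3487 at $k=1$ to 1.2529 at $k=2$ on a random 24-point
split). The test suite therefore asserts strict monotonicity only for
$\bar d_i(k)$ and near-universal (≥ 95 %) monotonicity for the derived
quantities.

## Behaviour on data with extreme outliers

```{r outliers}
model_cl <- fit_ad(sim, k = 12)
tail(model_cl$K)             # the two outliers have K_i = 0
tail(model_cl$fallback_mask) # ... and receive the fallback threshold
```

The two detached points are recognised as isolated ($K_i = 0$); their
fallback thresholds are the smallest in the model, so they contribute almost
no AD volume of their own, while every cluster member remains inside the
domain.

## Comparison methods

For benchmarking, the package also implements the classical ADs — bounding
box, PCA bounding box, convex hull (LP feasibility per query), centroid
distance and classical single-threshold kNN — and a family of density-based
ADs (fixed, LOO-optimized, variable and adaptive Gaussian kernels, the
compact-support Epanechnikov kernel, and a nearest-neighbour density), using
a percentile cutoff on leave-one-out training densities as the decision
rule. `compare_ad_methods()` runs everything on one train/test pair:

```{r compare}
qs <- simulate_qsar_dataset(seed = 7)
compare_ad_methods(qs$train, qs$test, include_density = FALSE)
```

## Reliability of retained predictions

`build_report()` ties the descriptor-space decision to the response domain:
it computes the predictive squared correlation
$Q^2 = 1 - \mathrm{MSE}_{\mathrm{test}} / \mathrm{MSD}_{\mathrm{train}}$
over the retained samples only, and the absolute standardized error
$SE_j = |y_j - \hat y_j| / s_Y$ for every scored sample (values above 2
flag response-domain outliers). On the simulated QSAR data — where a
fraction of the test set is deliberately displaced outside the training
support — excluding out-of-AD samples raises $Q^2$, and out-of-AD samples
show systematically larger standardized errors:

```{r report}
dec <- apply_ad(fit_ad(qs$train), qs$test)
rep <- build_report(dec, qs$test, qs$train$y, yhat_train = qs$train$y_hat)
rep
plot_se_vs_kj(rep)
```

## Defaults and their rationale

| Parameter | Default | Rationale |
|---|---|---|
| pretreatment | autoscaling | distances are meaningless across heterogeneous descriptor scales |
| quantile rule | linear (type 7) | R's standard convention; nearest-rank available |
| whisker factor `w` | 1.5 | the standard Tukey fence |
| `k` (no optimization) | `round(n^(1/3))` | common empirical rule for neighbour counts |
| hold-out fraction | 0.2 | standard validation split |
| iterations | 1000 | stable box-plot summaries (examples here use 200) |
| plateau tolerance | 2 % | "within sight of the maximum" for suggest_k |
| density cutoff | 5th percentile | mirrors the 95 % coverage convention of distance ADs |
| `SE` warning | 2 | conventional 2–3 sigma response-outlier band |

The synthetic QSAR generator deserves one note: its true signal is linear
plus a mild centred-quadratic term (coefficient 0.15, about 5 % of the
in-support response variance), and predictions come from an OLS fit on the
training data. This makes the fitted model — like any empirical QSAR model
— accurate on-support and progressively wrong off-support, which is exactly
the situation an AD is meant to detect. A `prediction = "oracle"` mode
(predictions equal to the noiseless signal) is provided for closed-form
checks of $Q^2$.

## Limitations

* All pairwise training distances are kept in memory: fine up to a few
  thousand samples, not intended for very large training sets.
* The convex hull is decided by per-query LP feasibility; in high dimension
  the hull is almost always too restrictive to be a useful AD anyway.
* Thresholds adapt to local density but are isotropic around each training
  sample; strongly anisotropic local structure is only captured through the
  global metric (e.g. Mahalanobis).
* The monotonicity caveat above: derived quantities grow with `k` in the
  typical case only.
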