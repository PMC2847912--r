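---
title: "Robust multiple comparisons of means under heteroscedasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust multiple comparisons of means under heteroscedasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxtcomp)
```

## The problem

Comparative studies in biology routinely ask which of several groups differ
in the mean of a quantitative trait. The classical answers — Tukey's
all-pairwise comparisons and Dunnett's many-to-one comparisons, both
calibrated by the studentized range or multivariate t under a *pooled*
variance — assume that every group has the same error variance and behave
poorly when that fails. The failure mode depends on how group sizes and
variances pair up: with larger variances in the larger groups ("positive
pairing") pooled-variance tests are conservative; with larger variances in
the *smaller* groups ("negative pairing") they become liberal and report
too many false positives. Unbalanced group sizes and unequal spreads are
the norm, not the exception, in observational biodiversity data.

`maxtcomp` implements a max-t procedure that drops the homoscedasticity
assumption: ordinary least squares still estimates the group means, but the
covariance of those estimates is taken from a heteroscedasticity-consistent
(HC) sandwich estimator, and all contrasts are referred *jointly* to the
distribution of the maximum absolute standardized statistic.

## Model and procedure

For groups $i = 1, \dots, p$ with $n_i$ observations, the one-way model is
fitted in cell-means form,

$$ y_{ij} = \beta_i + \varepsilon_{ij}, \qquad
   \hat\beta_i = \bar y_i, $$

so each coefficient is a group mean, each pairwise hypothesis is a
$\pm 1$ contrast row, and no reference-level bookkeeping is needed. The
intercept-plus-effects parameterisation $\mu + \gamma_i$ is deliberately
not used: $\mu$ and $\gamma_i$ are not separately identifiable and only
their sums enter any contrast.

A hypothesis family is a matrix $K$ ($k \times p$) with right-hand side
$m$: Tukey rows for all $p(p-1)/2$ pairs, Dunnett rows for $p - 1$
comparisons against a reference, or arbitrary rows parsed from symbolic
strings such as `"PE4 - PE3 = 0"`. Each contrast is standardized,

$$ t_k = \frac{c_k^\top \hat\beta - m_k}
             {\sqrt{c_k^\top \hat\Sigma c_k}}, $$

and the vector $(t_1, \dots, t_k)$ is treated as multivariate t with
correlation $R = D^{-1/2} K \hat\Sigma K^\top D^{-1/2}$ (with $D$ the
diagonal of $K \hat\Sigma K^\top$). Single-step adjusted p-values are
$1 - P(\max_j |T_j| \le |t_k|)$ and simultaneous $1-\alpha$ confidence
intervals are $c_k^\top\hat\beta \pm q_{1-\alpha} \cdot
\mathrm{se}(c_k^\top\hat\beta)$, with $q_{1-\alpha}$ the equicoordinate
quantile of the same joint distribution. Rejecting when the adjusted
p-value is below $\alpha$ controls the familywise error rate.

### Covariance estimators

`hc_covariance()` implements HC0–HC3, i.e.
$(X^\top X)^{-1} X^\top \mathrm{diag}(\omega_i) X (X^\top X)^{-1}$ with
$\omega_i = e_i^2$, $e_i^2 N/(N-p)$, $e_i^2/(1-h_{ii})$, or
$e_i^2/(1-h_{ii})^2$. In the one-way cell-means design the leverages are
$h_{ii} = 1/n_i$, the sandwich is diagonal, and HC3 reduces to the closed
form $\widehat{\mathrm{Var}}(\hat\beta_i) = \sum_j e_{ij}^2/(n_i-1)^2$,
which the package computes directly (tests verify it against the general
matrix accumulation and against an independent implementation). HC3 is the
default because it has the best small-sample behaviour of the family;
singleton groups make $h_{ii} = 1$ and are rejected for HC2/HC3 with an
explicit error rather than a silent division by zero. `ols_covariance()`
gives the classical pooled estimate $\hat\sigma^2 (X^\top X)^{-1}$ for
comparison.

### Degrees of freedom

The asymptotic theory behind the procedure is multivariate *normal*; in
finite samples, standard practice refers the statistics to a multivariate
*t* with the residual degrees of freedom $N - p$, and that is what
reproduces the reference numbers of the six-ecotype worked example (there
$N = 90$ complete observations, $p = 6$, so 84 df). The package therefore
defaults to `df = "residual"` and exposes `df = "normal"` (or any numeric
df) as an option. Note that the standard multivariate t shares a single
chi-square scale across components: even with an identity correlation the
components are dependent, so Šidák-type product formulas are exact only in
the normal limit.

## Computing the joint probabilities

`equicoordinate_probability()` evaluates $P(\max_j |T_j| \le t)$ with a
randomized quasi-Monte Carlo method over the separated-variable (Genz)
transform of the rectangle probability:

* Cholesky factorization of the (validated) correlation matrix with greedy
  variable reordering — at each step the variable with the smallest
  conditional probability is processed next — which reduces the variance
  of the integrand without changing the value;
* a Kronecker (Richtmyer) lattice with square-root-of-prime generators and
  a baker's transform, under `n_shifts` (default 12) independent uniform
  shifts; the spread of the per-shift means yields the reported
  `est_error` (a roughly 3-sigma bound);
* point doubling until `est_error` meets `accuracy`, capped at
  `max_points` per shift;
* for finite df, one extra lattice coordinate is mapped through the
  chi-square quantile function to the shared scale factor; these scale
  values are cached with the point set, so a quantile search or a family
  of p-values re-evaluates the integrand on one lattice at marginal cost.

`equicoordinate_quantile()` solves $P(q) = 1 - \alpha$ by bracketed root
search on a *fixed* point set (common random numbers), which makes the
objective monotone in $q$ at QMC precision; a family whose quantile cannot
be bracketed in $[0, 20]$ raises an error rather than returning a
meaningless extrapolation. Correlation matrices that are indefinite by a
numerical whisker (minimum eigenvalue in $(-10^{-8}, 0)$, which HC-based
correlations can produce) are repaired by eigenvalue clipping and diagonal
renormalization; anything worse is an error.

One seed governs the shifts of every probability and quantile evaluation
inside a single analysis, so the reported p-values and intervals are
mutually coherent: an interval excludes $m_k$ exactly when the adjusted
p-value is below $\alpha$.

Default accuracies differ by role: `1e-4` for the standalone probability
and quantile functions (four-decimal reproducibility at desk scale),
`1e-3` for the p-values of a full analysis (well below the precision at
which such tables are read), and `2e-3` inside the simulation engine,
where only the reject/don't-reject decision matters and the binomial noise
of 1000 replicates dominates. Adjusted p-values below $10^{-3}$ are
*displayed* as `<0.001` in the text report but stored numerically.

## The simulation engine

`run_study()` reproduces the familywise error rate / power experiment:
four-group unbalanced layouts with allocation $N \cdot (0.1, 0.2, 0.3,
0.4)$, group standard deviations $(1,1,1,1)$ under homoscedasticity
(model A), $(0.5, 1, 1.5, 2)$ aligned with the group sizes (models B and
D — smaller variances in the smaller groups) or reversed (models C and E),
normal errors for A–C and right-skewed errors for D–E, $N \in \{40, 80,
160\}$, 1000 datasets per setting, and a 41-point grid of offsets
$\delta$ added to the group-1 mean spanning $[0, 2\max\sigma]$. The
original experiment's exact constants are not all published; these
defaults satisfy every stated qualitative constraint (unbalanced
allocation, positive versus negative pairing of sizes and variances) and
are ordinary config-level choices, overridable through `scenario()`.

The right-skewed law is a standardized shifted exponential,
$\sigma_i(\mathrm{Exp}(1) - 1)$: the simplest right-skewed error with
exact mean 0 and standard deviation $\sigma_i$ (skewness 2). Each
(replicate, delta) pair gets its own substream seed derived from the
master seed, so any replicate is reproducible in isolation and all methods
see identical datasets. The same replicates serve both summaries: the
FWER is the share of datasets with at least one rejected true pairwise
null (all pairs at $\delta = 0$; pairs not involving group 1 otherwise),
and per-pair power is the rejection rate of each group-1 pair — at
$\delta = 0$ those rows are per-pair type-I error rates.

For speed, the engine does not compute every adjusted p-value: it visits
the statistics in decreasing order and stops at the first non-rejection,
which is equivalent because the max-|T| probability is monotone in the
threshold on a common lattice. Under a true null this costs roughly one
probability evaluation per dataset.

What the generator does *not* emulate: within-group correlation, outliers
beyond the exponential tail, measurement error structure, more than one
factor, or group counts other than those configured. Passing simulation
tests therefore demonstrates correct error-rate behaviour under clean
independent sampling, not robustness to violations outside the model.

## Worked example

The package ships no data of its own; the six-ecotype fatty-acid table
used throughout the documentation comes from the `multcomp` package
(`data("fattyacid")`: 93 rows, of which 3 have missing responses that the
default `na_action = "drop"` removes with a message).

```{r example, eval = FALSE}
data("fattyacid", package = "multcomp")
res <- max_t_test(fattyacid, group = PE, value = FA,
                  contrasts = "tukey", vcov = "HC3", seed = 1)
res           # printed report with significance marks
tidy(res)     # one row per contrast
glance(res)   # family-level summary
autoplot(res) # simultaneous confidence intervals
```

Six of the fifteen pairwise comparisons are significant at the 5% family
level under HC3; the 95% equicoordinate quantile is about 2.89 with 84
degrees of freedom.

## Numerical choices and edge cases

* Group labels are ordered lexicographically at ingest; every contrast
  label (`"PE5 - PE4"`) derives from that order, coded later minus
  earlier.
* Missing or non-finite responses: dropped with a logged count by default,
  hard error on request.
* Zero residual variance in every group makes every contrast standard
  error zero and is reported as "degenerate contrast variance" rather than
  producing infinite statistics.
* All-equal group means give $t = 0$ and adjusted p-values of exactly 1.
* `alpha = 1` in a scenario means "always reject", used to sanity-check
  the error-rate machinery.
* Symbolic contrasts accept decimal coefficients (`"0.5*A + 0.5*B - C"`)
  although pairwise analyses only need $\pm 1$.

## Problem sizes

The shipped tests run the worked example once (90 observations, 15
contrasts), desk-scale closed-form and quadrature oracles, and simulation
blocks of 1000 replicates at $N = 80$ and $N = 160$ for the error-rate
claims plus three mid-grid deltas at $N = 80$ for the power comparison
— sizes chosen so the full suite completes comfortably on a single CPU
while keeping binomial standard errors near 0.007.

## Limitations

* One factor, no covariates, no weighting; generalized and mixed models
  are out of scope.
* Two-sided alternatives only, matching the max-|T| statistic; one-sided
  max-t is a straightforward extension not implemented here.
* Single-step adjustment only; step-down refinements and resampling-based
  adjustments are not provided.
* The QMC error estimate is statistical, not a hard bound; `est_error` is
  calibrated as roughly 3 standard errors across lattice randomizations.
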