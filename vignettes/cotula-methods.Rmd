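---
title: "Methods: coupling-tuning-latent models and their inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling-tuning-latent models and their inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotula)
```

## The models

`cotula` implements linear-Gaussian models of a recorded neural population in
which a unit's activity reflects three influences: *functional coupling* to
the other recorded units, *tuning* to an observed external variable, and a
low-dimensional *latent* state standing in for everything that was not
recorded.

In the **static** (trial-level) form the population has $N+1$ units, one of
which — the *target*, by convention column 1 wherever the population is a
single matrix — is modeled conditionally on the rest:

$$y_i = \mathbf a^\top \mathbf y_{\neg i} + \mathbf b^\top \mathbf x
      + \mathbf l^\top \mathbf z + \psi_i,\qquad
  \mathbf y_{\neg i} = B^\top \mathbf x + L^\top \mathbf z
      + \boldsymbol\psi_{\neg i},\qquad
  \mathbf z \sim \mathcal N(0, I_K).$$

Private noise is independent Gaussian with variances $\psi_i$ and
$\Psi_{\neg i}$; dropping the latent terms gives the plain CoTu regression.
Because everything is jointly Gaussian given $\mathbf x$, the model admits a
closed-form joint covariance and precision for $(y_i, \mathbf y_{\neg i},
\mathbf z)$ (`joint_moments()`, `precision_matrix()`), an exact marginal
likelihood of the observed block (`marginal_loglik()`), and an exact E-step
by Gaussian conditioning.

The **dynamic** form drops the target/non-target asymmetry and couples $N$
units through a VAR(1):

$$\mathbf y_t = A \mathbf y_{t-1} + B \mathbf x_t + L \mathbf z_t
    + \boldsymbol\psi_t,\qquad
  \mathbf z_t = G\mathbf z_{t-1} + \boldsymbol\eta_t,\ \boldsymbol\eta_t
    \sim \mathcal N(0, I_K),\qquad
  \mathbf x_t = H \mathbf x_{t-1} + \boldsymbol\eta^x_t.$$

Stationarity requires spectral radii of $A$, $G$, $H$ below 1 and is enforced
at construction. The latent innovation covariance is pinned to $I_K$ (it is
not separately identifiable from the scale of $L$); the stimulus innovation
variance defaults to $1 - h^2$ per coordinate so the stationary stimulus
variance is 1 regardless of $H$, which keeps tuning strengths comparable
across experimental conditions that differ only in temporal correlation.

## Structural non-identifiability and the transform

The static CoTuLa likelihood is invariant under a $K$-parameter family of
transformations that trade the target's latent loading against its coupling,
tuning and private variance. With
$P = (\Pi_{\neg i} + L^\top L)^{-1}$ (the non-target variability precision)
and $W = I_K - L P L^\top$,

$$\mathbf l' = \mathbf l + \boldsymbol\delta,\quad
  \mathbf a' = \mathbf a - P L^\top \boldsymbol\delta,\quad
  \mathbf b' = \mathbf b + B P L^\top \boldsymbol\delta,\quad
  \psi' = \psi - 2\,\mathbf l^\top W \boldsymbol\delta
        - \boldsymbol\delta^\top W \boldsymbol\delta.$$

The quadratic metric $W$ is forced by the requirement that the observed
$(y_i, \mathbf y_{\neg i})$ covariance — and hence the likelihood on every
dataset — be exactly invariant; one can check directly that the target
variance changes by $-\boldsymbol\delta^\top(W_{\text{used}} - W)
\boldsymbol\delta$ if any other quadratic form is used. The test suite
asserts invariance to $10^{-8}$ relative on random models; in practice it
holds to machine precision. For $K = 1$, $\psi'(\delta)$ is a downward
parabola with curvature $w = 1 - LPL^\top \in (0, 1]$, so the admissible set
($\psi' \ge 0$) is an interval whose endpoints `transform_family()` uses to
lay out equally spaced family members; its apex sits at $\delta^* = -l$,
i.e. exactly at the member with **zero target latent loading** and maximal
private variance.

Sparsity restores identifiability: stacking the rows of $Q = PL^\top$ and
$R = BQ$ indexed by the zero entries of $\mathbf a$ and $\mathbf b$ into $S$,
the only support-preserving direction is $\boldsymbol\delta = 0$ exactly when
$S$ has full column rank $K$ (which requires at least $K$ zero entries).
`theorem1_check()` reports both the counting condition and the computed rank
with an SVD threshold of $\max(\dim) \cdot \varepsilon_{\text{mach}} \cdot
\sigma_{\max}$, plus an orthonormal basis of the surviving null space, so the
two conditions can be inspected separately.

## Inference

**CoTu**: restricted ordinary least squares; off-support coefficients are
exactly zero (`fit_cotu_ols()`, `fit_dynamic_cotu_ols()`).

**Static CoTuLa EM**: the E-step conditions the latent on each trial
($\Sigma_q^{-1} = I_K + \tilde L \Pi^{-1} \tilde L^\top$ shared across
trials, per-trial means linear in the structural residuals). The M-step is a
joint restricted least-squares solve for $(\mathbf a, \mathbf b, \mathbf l)$
against the predictors $(\mathbf y_{\neg i}, \mathbf x, \mu^{(d)})$ with the
Gram matrix augmented by $D\,\Sigma_q$ on the latent block, row-wise solves
for $(B, L)$, and expected residual quadratics for the variances. The joint
(rather than alternating) target-row solve was chosen because it maximizes
the expected complete likelihood in one step; a numeric-gradient oracle in
the tests verifies stationarity of the objective at the returned parameters.
Defaults: relative log-likelihood tolerance `1e-8`, `max_iter = 500`,
variance floor `1e-8`. Initialization is deterministic and data-driven —
restricted OLS for the regression parameters, loadings from the top-$K$
eigenvectors of the per-unit residual covariance scaled by root eigenvalues,
variances from the residuals; random restarts perturb this with seeded
Gaussian noise (sd 0.1). Intercepts, when requested, enter every regression
as an always-free column.

**Dynamic CoTuLa EM**: the latent posterior is a block-tridiagonal Gaussian;
its precision has diagonal blocks $L^\top\Sigma^{-1}L + I_K + G^\top G$ (edge
blocks without the $G^\top G$ term) and off-diagonal blocks $-G^\top$. The
E-step computes the exact marginals in $O(TK^3)$ with a Kalman filter and
RTS smoother (compiled, RcppArmadillo), keeping only the diagonal and
first-off-diagonal covariance blocks — precisely the blocks the expected
log-likelihood needs. A dense $TK \times TK$ inversion oracle in the test
suite confirms block-level agreement to $10^{-9}$ on systems up to $T = 20$.
The M-step performs row-wise restricted solves for $(A, B, L)$ with the
latent Gram correction, expected-residual variances (diagonal $\Sigma$,
matching the i.i.d. private-noise assumption), and a latent lag regression
for $G$ using the smoothed first/second/cross moments. Updates of $A$ and
$G$ are rescaled to spectral radius $< 1$ in the rare case an intermediate
iterate leaves the stationary region. The convergence trace is the exact
observed-data log-likelihood from the filter (tolerance `1e-8`,
`max_iter = 200`).

**Edge handling**: the first observed sample conditions the chain — the
first transition is dropped from the likelihood and the latent chain starts
from its $\mathcal N(0, I_K)$ prior — so all posterior and residual arrays
have $T-1$ time blocks aligned to times $2..T$.

**Selection.** Two-stage inference separates support recovery from
estimation. For static models, `infer_support_static()` is a
union-of-intersections-style *approximation*: 20 bootstrap resamples of a
48-point log-spaced lasso path (via `glmnet`), intersection of supports per
regularization level, and the level chosen by out-of-sample $R^2$ of a
restricted OLS refit on a 10% holdout. For dynamic models,
`infer_support_dynamic()` normalizes each OLS coefficient by the median
absolute deviation (about zero) of its matrix's entries and keeps entries
above 2.0 MADs; this exploits the fact that, in sparse matrices, the MAD is
set by the estimation noise of the truly-zero entries, so it degrades when
fewer than about 60% of entries are zero.

## The synthetic generators — what they emulate and what not

The static sweep generator draws sparse models (default half of the coupling
and tuning entries exactly zero, nonzero values $\mathcal N(\text{cell
mean}, 0.1^2)$) and imposes uniform noise correlations through a $K = 1$
equal-loading construction: every unit gets loading $\sqrt\rho$ and private
variance $1-\rho$, so each pairwise residual correlation is $\rho$ (default
0.10) and each residual variance is 1. This emulates the magnitude of noise
correlations in cortical recordings but not their heterogeneity in sign and
strength, their stimulus dependence, or non-Gaussian (point-process) spiking
— so passing tests demonstrate correct inference under the stated
linear-Gaussian conditions, not robustness to real spike trains. Stimuli are
i.i.d. standard normal by default (one-hot categorical available for
tuning-curve designs). The dynamic four-condition suite crosses stimulus and
latent AR coefficients over $\{0, 0.6\}$, with sparse coupling (diagonal
near 0.4, a quarter of off-diagonals near 0.2, spectral radius capped at
0.85), unit loadings and unit private variance.

## Problem sizes in the shipped tests

The test suite runs the experiments at desk scale, chosen to finish in
minutes while leaving the Monte-Carlo error well below the asserted margins:
the mean sweep on a $3\times3$ grid of means in $[-1,1]$ with 3 models per
cell, 5 datasets per model, $D = 2000$ trials split over 3 folds; the
identifiability experiment with 30 family-spanning initializations at
$D = 2000$; the univariate error-law grid at $T = 2\times10^5$ with 5
replicate series per point; and the dynamic four-condition suite at
$T = 5000$ with 50 realizations for the OLS signature and 8 for the
oracle-EM mitigation. Larger designs are reachable through
`sweep_config()` / `dynamic_conditions_config()`.

## What non-identifiability does to EM — and a caveat

The package reproduces the central phenomenon: on positively correlated data,
latent-blind OLS and unselected EM overestimate coupling and underestimate
tuning magnitude *systematically*, while estimation restricted to the true
support is essentially error-free, and inferred selection sits in between.

One subtlety deserves emphasis. Because the likelihood is **exactly** flat
along the identifiability family — for every dataset, not just in
expectation — every family member of an empirical optimum is a fixed point
of EM, and a likelihood-monotone EM has no tangential motion along the
family. Consequently, initializations that *span* a family converge to
spread-out points whose family coordinate tracks the initialization
(`run_identifiability_experiment()` makes this visible; it runs a fixed
iteration budget with the tolerance disabled, since a likelihood-change
stopping rule terminates immediately in flat directions). Clustering of
estimates arises instead from the initialization scheme: data-driven
initializations start the target loading near zero, which at $K=1$ is
exactly the family apex (maximal private variance), so random restarts —
Gaussian perturbations of that initialization — consistently land near the
apex and deliver the signature "low variance, systematic error" outcome. A
procedure whose restarts cluster at the apex from *arbitrary* family
positions would need some force beyond this likelihood (e.g. shrinkage on
the loading); the package deliberately does not add one.

## Numerical choices and degenerate inputs

- Admissibility of a transform direction is checked as $\psi' \ge
  -10^{-12}$; family endpoints are generated with $\psi' = 0$ and, when used
  as EM initializations, variances are floored at `1e-8` (the E-step needs
  positive private variances).
- `precision_matrix()` requires strictly positive private variances and
  refuses singular inputs; `marginal_loglik()` rejects non-positive-definite
  observed covariances with a diagnostic.
- Normalized errors $(\hat\theta - \theta)/\theta$ are computed on truly
  nonzero entries only; zero-truth entries are excluded and counted.
  Magnitude-attenuation claims are therefore sign-split: attenuation means
  *raw* error opposite in sign to the parameter mean, equivalently negative
  normalized error for either sign of the mean.
- The sweep aggregation is mean over datasets and folds, then median over
  models per parameter position, then median over parameters.
- All experiment drivers derive per-unit seeds from the master seed with a
  counter scheme (`spawn_seed()`), so any slice of a sweep is reproducible
  in isolation; reports round-trip through CSV/JSON at full double
  precision.

## Known limitations

- Gaussian responses only; no Poisson/point-process variant.
- Static selection is an approximation to union-of-intersections lasso, not
  a reimplementation; dynamic selection is a simple MAD cutoff.
- The closed-form error expressions cover the univariate dynamic model; the
  multivariate case is handled only numerically.
- Dynamic fitting assumes a single uninterrupted series (no trial
  structure, no missing data) and diagonal private noise.
- `transform_family()` supports $K = 1$ (the family is a $K$-manifold;
  only the scalar case admits the equally-spaced-interval construction).
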