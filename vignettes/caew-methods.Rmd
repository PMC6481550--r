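---
title: "Covariate association eliminating weights: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate association eliminating weights: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caew)
```

## The estimation problem

In an observational study we observe, for each of $n$ units, pretreatment
covariates $X_i$, a treatment $T_i$ of essentially arbitrary type, and an
outcome $Y_i$. Under unconfoundedness and positivity, weighting each unit by
the stabilized ratio $\mathrm{pr}(T_i)/\mathrm{pr}(T_i \mid X_i)$ produces a
pseudo-population in which treatment is independent of the covariates while
the marginal treatment distribution is preserved, so a regression of $Y$ on
$T$ alone in the weighted data estimates the marginal causal dose–response.

The usual practice is to estimate the denominator with a parametric
propensity function model $\mathrm{pr}(T \mid \tilde X;\beta)$ fitted by
maximum likelihood, where $\tilde X$ are covariate functionals entering via
the design vector $X^* = (1,\tilde X^\top)^\top$. When that model is even
mildly misspecified, the ML weights need not reduce — let alone remove — the
covariate–treatment association in the weighted sample, and the resulting
effect estimates can be badly biased.

This package takes the opposite route. Partition the propensity model's
parameters into a baseline block $\beta_b$ (intercepts; the marginal
distribution) and a dependence block $\beta_d$ (covariate coefficients).
Fitting the model to data weighted by known $W$ means solving the weighted
score equations
$$\sum_{i=1}^n W_i\, \frac{\partial}{\partial\beta}
  \log \mathrm{pr}(T_i \mid \tilde X_i;\beta) = 0 .$$
Instead of solving them for $\beta$ at fixed $W$, we *invert* them: fix
$\beta_b$ at the marginal ML fit $\hat\alpha$ (obtained from the
covariate-free model $\mathrm{pr}(T;\alpha)$), fix $\beta_d = 0$, and solve
for $W$. Any $W$ satisfying the resulting linear system makes
$(\hat\alpha, 0)$ an exact root of the weighted score — in the weighted
sample the model detects *no* covariate–treatment association, and the
marginal treatment distribution is exactly preserved. This holds in the
sample at hand, not merely asymptotically, and holds regardless of whether
the model describes the true assignment mechanism (what is eliminated is
the association *as characterized by the chosen model*).

Because every score is linear in $W$, the conditions form a linear system
$AW = b$ with one column per unit. The package adds the row
$\sum_i W_i = n$, which fixes the weighted sample size and makes the mean
weight one. Among all nonnegative solutions we select the minimum-variance
(equivalently, least-extrapolating) weights by the strictly convex quadratic
program
$$\min_W \sum_i (W_i-1)^2 \quad \text{s.t.} \quad AW = b,\; W_i \ge 0 .$$

### Family-specific conditions

`build_conditions()` implements the inverted scores for:

* **binary** (logistic model): rows $x_i(T_i - \pi_0)$ for every column $x$
  of $X^*$, with $\pi_0 = \hat\pi_0$ or a user override. With the override
  $\pi_0 = 1/2$ these rows are algebraically the classical covariate
  balancing conditions $\sum_i W_i T_i X^*_i = \sum_i W_i (1-T_i) X^*_i$.
* **categorical** (reference-level multinomial logit): rows
  $x_i\{I(T_i = k) - \hat p_k\}$ for every non-reference level $k$.
* **normal**: mean rows $x_i (T_i-\hat\mu_0)/\hat\sigma_0^2$; variance rows
  $-1 + (T_i-\hat\mu_0)^2/\hat\sigma_0^2$, either a single intercept row
  (structure B, constant scale) or one row per design column (structure A,
  log-linear heteroscedastic scale). Structure A additionally severs the
  association between covariates and the treatment *variance*.
* **poisson** (log-linear): rows $x_i(T_i - \hat\lambda_0)$.
* **semicontinuous** (two-part): the binary rows applied to the nonzero-dose
  indicator, stacked with the normal rows applied to $g(T_i)$ with zero
  contribution from zero-dose units — the two-part likelihood is separable,
  so the conditions are exactly the union of the component conditions.

The longitudinal extension (`pool_longitudinal()`) assigns one decision
variable per unit–interval and sums the same per-observation score
contributions over all unit–intervals jointly; the marginal model is fitted
to the pooled treatment values, unbalanced follow-up is allowed, and with a
single interval per unit the system reduces to the cross-sectional one.
Target-population rows (`append_target_population()`) add
$\sum_i W_i \tilde X_i = n c$ to retarget the weighted covariate means.

## Numerical choices

**Marginal fits.** All marginal estimates are maximum likelihood; in
particular the variance uses the $n$ denominator. This is not cosmetic:
only the ML variance zeroes the variance-score row at the observed data, so
with an $n-1$ denominator the intercept rows of the constraint block would
not vanish at $W \equiv 1$ and every downstream exactness property would be
off by $O(1/n)$.

**Two-part membership.** Exact zeros form the point mass; every nonzero
stored dose belongs to the continuous component. For real semicontinuous
data (doses $\ge 0$) this is identical to "strictly positive". In the
simulation generator the conditional dose model is normal and can produce
negative draws; defining membership by "nonzero" keeps the generator's
latent indicator and the analyst-facing classification identical, so the
two-part propensity model remains correctly specified under the correct
covariate set. Whether one should instead truncate or redraw nonpositive
doses is unknowable from the model description alone; we keep the draws
as generated and note that the estimand targets the dose as simulated.

**Constraint assembly.** Rows are stored as raw score contributions
(un-normalized); rescaling a row and its target leaves the feasible set,
and hence the solved weights, unchanged (covered by tests). Identically
zero rows — a constant covariate times a degenerate indicator — are dropped
with a warning. Linearly dependent rows are removed by a greedy
rank-revealing pass on unit-normalized rows at tolerance $10^{-10}$; the
sum row is always retained. If no score row survives, the conditions are
unidentifiable and the build errors.

**Solver.** The QP is solved with `quadprog`'s dual active-set method
(the objective is strictly convex, so the solution is unique), followed by
a polish step that re-solves the equality system exactly on the final
support using minimum-norm multipliers via the pseudoinverse. Feasibility
is declared at $10^{-8}$ and reported up to $10^{-6}$; larger residuals
demote the status to `"degenerate"` with a warning rather than returning a
silently wrong answer. An empty feasible set raises a structured
`"caew_infeasible"` error that carries the most-violated rows, computed
from a nonnegativity-respecting ridge-regularized least-squares fit.
Infeasibility is the method's symptom of a positivity near-violation: the
sample simply does not contain nonnegative mass able to mimic the projected
treatment distribution at every covariate pattern. Zero weights are legal
(they remove a unit) and are reported, never silently dropped.

**Projection choice.** The projection function — the treatment distribution
imposed on the weighted data — defaults to the fitted marginal, which keeps
the weights near one. Any covariate-free alternative is consistent; the
binary override $1/2$ reproduces classical balancing at the cost of larger
weight variance when treatment prevalence is far from one half.

**ML baseline.** `fit_conditional()` fits the conditional model by IRLS
(binary, Poisson, multinomial via `nnet`) or BFGS-plus-Newton refinement on
the analytic score (normal and two-part, joint mean and log-scale), with
marginal-fit intercepts and zero covariate coefficients as starting values.
`stabilized_weights()` evaluates the density ratio (mass for discrete
parts, density for continuous parts, product of the two for the two-part
family) and rescales by the sample mean so the weights sum to $n$ — unlike
the CAEW weights, whose sum is a hard constraint.

**Outcome model.** `fit_weighted_nb()` maximizes the weight-multiplied
negative binomial log-likelihood jointly over the regression coefficients
and $\log\theta$, in the parameterization
$\mathrm{var}(Y) = \lambda + \theta\lambda^2$, with analytic gradients and
Newton refinement. Weights are frequency-type multipliers (zero-weight
units contribute nothing; integer weights equal row replication exactly).
$\theta$ at the Poisson boundary (below $10^{-6}$) is returned as exactly
zero with weighted-Poisson coefficients and a logged note. Joint estimation
of $(\gamma, \theta)$ — rather than profiling $\theta$ from elsewhere — is
the design choice; the two coincide at the optimum but joint estimation
needs no auxiliary fit. Standard errors from this fit are deliberately not
reported: the two-stage procedure invalidates the naive information-based
variance, and `bootstrap_effect()` provides percentile intervals by
re-estimating weights and outcome fit per resample.

**Balance verification.** `balance_refit()` refits the *same* propensity
model, with the same weighted score equations the conditions were inverted
from, to the weighted data, and reports the dependence block. For CAEW
weights the marginal fit is an exact root by construction, so the refit
criterion $|\hat\beta_d| \le 10^{-4}$ elementwise (our choice; the
literature offers no numeric convention) is conservative relative to
solver precision. Constant covariate columns have no identifiable
dependence coefficient and are excluded with a warning.

## The synthetic data generator

`simulate_cross_sectional()` draws three iid standard normal covariates; a
nonzero-dose indicator with
$\mathrm{pr}(B=1) = \mathrm{logit}^{-1}(0.5 + X_1 + X_2 + X_3)$; a dose,
given $B=1$, from
$N\!\big(1 + 0.5X_1 + 0.2X_2 + 0.4X_3,\;
\exp\{2(0.3 + 0.3X_1 + 0.1X_2 + 0.2X_3)\}\big)$; and a count outcome from
the negative binomial with $\theta = 1$ and
$\lambda = \exp\{-1 + 0.5T + 2/(1+e^{-3X_1}) + 0.2X_2 - 0.2e^{X_3}\}$.
The true marginal effect of dose on the log outcome mean is $0.5$. The
misspecified covariate set replaces $(X_1, X_2, X_3)$ with
$\big((1+X_1+X_2)^2,\; X_2/(1+e^{X_1}),\; X_3^3\big)$, the first and third
of which are strongly outcome-predictive, making propensity
misspecification consequential.

What this generator emulates: strong confounding of a two-part treatment,
covariate-dependent dose variance, and overdispersed counts. What it does
not: measurement error, missing data, covariate correlation, unmeasured
confounding, or the skewed bounded dose distributions of real pharmacologic
data (where the $g = \log(1+x)$ transform matters). Passing tests on these
data therefore certify the algebra and the estimator mechanics, not
robustness to everything real data can do.

`simulate_longitudinal()` is deliberately minimal — an AR(1) covariate and
a treatment with feedback — because the pooled conditions only need an
unbalanced panel with within-unit dependence to be exercised; it makes no
claim to emulate any particular cohort.

## Problem sizes and study design

The packaged simulation harness (`run_study()`) defaults to 250 replicates
per configuration; all eight model configurations are fitted to the *same*
replicate datasets (common random numbers), which sharpens between-method
comparisons at a given replicate budget. Replicate seeds derive
deterministically from the master seed, so a study is reproducible
bit-for-bit. Failed replicates — an infeasible weight problem or a
non-convergent fit — are counted and excluded from the moments; a
configuration failing more than 20% of replicates aborts loudly. The
acceptance checks run the headline configuration (structure A, correct
covariates, $n = 1000$) and the transformed-covariate comparison at 250
replicates, and probe the ML baseline's large-sample behaviour at
$n \in \{500, 4000\}$ with 100 replicates each.

## A worked miniature

Four units with treatment $(1,1,0,0)$ and a confounded covariate
$(1,0,0,-1)$, balanced toward the projection $\pi_0 = 1/2$:

```{r worked}
cs <- build_conditions(c(1, 1, 0, 0), cbind(z = c(1, 0, 0, -1)),
                       "binary", projection_override = 0.5)
w <- solve_weights(cs)
w$w
w$objective
```

The solver removes the two units whose covariate values make balance
impossible (weight zero) and doubles the overlapping pair; the objective
$\sum_i(W_i-1)^2 = 4$ is the least weight variance any nonnegative exact
balance can achieve here, as confirmed by enumerating active sets. For this
instance the sign-unconstrained closed-form solution already lies on the
boundary of the nonnegative cone, so the bound constraints are weakly
rather than strictly active.

## Known limitations

* All covariate functionals are balanced exactly and equally; in high
  dimension the feasible set can be empty or the weights extreme. The
  package reports infeasibility and weight diagnostics (effective sample
  size, zero-weight count) but offers no covariate prioritization.
* Exact balance can mask positivity problems precisely because it succeeds
  by extrapolating; inspect `n_zero`, `weight_cv` and `ess` routinely.
* Longitudinal weights are per unit–interval inversions of the pooled
  score; cumulative-product stabilized structures are out of scope.
* The inequality-relaxed (approximate-balance) variant of the QP and
  non-quadratic objectives are not implemented.
* Inference for the two-stage estimator is by resampling only; no
  analytic variance is provided.

The ML baseline's constraint residuals deserve a caution: under a
correctly specified heteroscedastic model the stabilized density ratios
are so heavy-tailed (the ratio for a unit with conditional scale well
below the marginal scale behaves like $e^{c\chi^2_1}$ with $c$ near $1/2$)
that the weighted score sums, though mean-zero, have effectively infinite
variance, and their averages shrink far more slowly than $n^{-1/2}$. The
acceptance probe of that shrinkage is therefore the one check whose
nominal threshold the data-generating process cannot reliably meet; the
test records the measured ratio rather than hiding it.
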