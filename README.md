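# caew — covariate association eliminating weights

`caew` estimates causal treatment effects from observational data by
weighting, for treatments of essentially any type: binary, categorical,
normal (with covariate-dependent or constant variance), Poisson counts, and
semicontinuous two-part treatments (a point mass at zero plus a continuous
dose), with a pooled extension to longitudinal time-varying treatments. It
is aimed at biostatisticians and epidemiologists fitting marginal
structural outcome models — e.g. the effect of drug dose on a damage count
— where the standard maximum-likelihood inverse-probability weights are
fragile under propensity model misspecification.

## The idea

Let $\mathrm{pr}(T \mid \tilde X; \beta)$ be a chosen propensity function
model, with parameters partitioned into a baseline block $\beta_b$
(intercepts) and a dependence block $\beta_d$ (covariate coefficients).
Fitting this model to data weighted by $W$ solves the weighted score
equations. `caew` *inverts* them: it fixes $\beta_b = \hat\alpha$ (the
covariate-free marginal ML fit) and $\beta_d = 0$, and solves for the
weights,

$$\sum_{i=1}^{n} W_i \,\frac{\partial}{\partial \beta}
 \log \mathrm{pr}(T_i \mid \tilde X_i;\beta)
 \Big|_{\beta_b=\hat\alpha,\;\beta_d=0} = 0 ,$$

so that after weighting the model finds *no* covariate–treatment
association and the marginal treatment distribution is preserved — exactly,
in the sample at hand. These score conditions are linear in $W$; together
with $\sum_i W_i = n$ they define the feasible set of a strictly convex
quadratic program

$$\min_W \sum_i (W_i - 1)^2
 \quad\text{s.t.}\quad AW = b,\; W_i \ge 0,$$

whose unique solution is the minimum-variance (least-extrapolating)
nonnegative weight vector. Classical covariate balancing conditions for
binary and continuous treatments are special cases of the constraint rows.
The package also provides the maximum-likelihood stabilized weights
$W_i = \mathrm{pr}(T_i;\hat\alpha)/\mathrm{pr}(T_i\mid\tilde X_i;\hat\beta)$
as a baseline, a weighted negative binomial outcome model
($\mathrm{var}(Y)=\lambda+\theta\lambda^2$), balance diagnostics by
weighted refitting, target-population retargeting, and a simulation-study
harness.

## Worked example

Simulate the benchmark semicontinuous-treatment process (three standard
normal confounders, logistic dose indicator, heteroscedastic normal dose,
negative binomial outcome with a true dose effect of 0.5 on the log mean),
then estimate the effect with CAEW weights:

```r
library(caew)
d   <- simulate_cross_sectional(1000, seed = 42)
x   <- as.matrix(d[c("X1", "X2", "X3")])
fam <- treatment_family("semicontinuous", structure = "A", g = "identity")

cs <- build_conditions(d$T, design_matrix(x), fam)
cs
#> CAEW constraint system: 13 rows x 1000 units (family: semicontinuous)
#> rows: binary:(Intercept), binary:X1, binary:X2, binary:X3, mean:(Intercept),
#>   mean:X1, mean:X2, mean:X3, var:(Intercept), var:X1, var:X2, var:X3, sum

w <- solve_weights(cs)
w
#> Weights (caew): n = 1000, status = optimal
#>   objective sum((w-1)^2) = 1107, zero weights = 221
#>   max constraint residual = 6e-13

balance_refit(d$T, design_matrix(x), w, fam)
#> Balance report
#>   max |beta_d| after weighting: 5.937e-13 (balanced at 1e-4)
#>   effective sample size: 474.6   zero weights: 221   weight CV: 1.053

fit_weighted_nb(d$Y, d$T, w)
#> Weighted negative binomial outcome fit (linear_in_T)
#> (Intercept)           T
#>      0.0824      0.4929
#>   theta = 1.587  loglik = -1742  converged: TRUE
```

The treatment coefficient `0.4929` is the estimated marginal effect of one
dose unit on the log outcome mean (truth: `0.5`); `theta = 1.587` is the
estimated overdispersion. Refitting the same propensity model to the
weighted data returns dependence coefficients of order `1e-13`: the
covariate association has been removed exactly, with 221 units receiving
zero weight and an effective sample size of about 475. On the same dataset
the ML stabilized weights leave a residual dependence coefficient of
`0.28` and give `0.539` for the effect:

```r
wml <- estimate_weights(d$T, x, fam, approach = "ml")
fit_weighted_nb(d$Y, d$T, wml)$gamma1
#> [1] 0.5389866
```

A thin command-line front end (`inst/cli/caew`) exposes `simulate`,
`weights`, `balance`, `outcome` and `study` subcommands over CSV files.

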