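#' Simulate a cross-sectional semicontinuous-treatment dataset
#'
#' Generates the benchmark data-generating process used throughout the
#' package's simulation study: three independent standard normal
#' pretreatment covariates; a semicontinuous treatment whose nonzero-dose
#' indicator is Bernoulli with
#' \eqn{\mathrm{pr}(B=1) = 1/[1+\exp\{-(0.5 + X_1 + X_2 + X_3)\}]} and
#' whose dose, when \eqn{B=1}, is normal with mean
#' \eqn{1 + 0.5 X_1 + 0.2 X_2 + 0.4 X_3} and standard deviation
#' \eqn{\exp(0.3 + 0.3 X_1 + 0.1 X_2 + 0.2 X_3)}; and a negative binomial
#' outcome with overdispersion \eqn{\theta = 1} and mean
#' \eqn{\lambda = \exp[-1 + 0.5 T + 2/\{1+\exp(-3 X_1)\} + 0.2 X_2 -
#' 0.2 \exp(X_3)]}.  The true marginal treatment effect on the log mean is
#' `0.5` per unit of dose.
#'
#' @param n sample size.
#' @param seed integer seed; the dataset is a deterministic function of
#'   `(n, seed)`.
#'
#' @return A `data.frame` with columns `X1, X2, X3` (covariates), `B`
#'   (latent nonzero-dose indicator), `T` (treatment; exactly 0 when
#'   `B = 0`), `Y` (count outcome).
#'
#' @details The dose draw is kept exactly as generated even when it is not
#'   positive (the normal dose model has unbounded support); membership in
#'   the continuous component is defined by `T != 0`, which coincides with
#'   `B` almost surely.  See the methods vignette for discussion.
#' @examples
#' d <- simulate_cross_sectional(200, seed = 1)
#' mean(d$T != 0)  # about E[pr(B=1)] ~ 0.58
#' @export
simulate_cross_sectional <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  X1 <- stats::rnorm(n); X2 <- stats::rnorm(n); X3 <- stats::rnorm(n)
  pB <- stats::plogis(0.5 + X1 + X2 + X3)
  B <- stats::rbinom(n, 1, pB)
  tpos <- stats::rnorm(n, mean = 1 + 0.5 * X1 + 0.2 * X2 + 0.4 * X3,
                       sd = exp(0.3 + 0.3 * X1 + 0.1 * X2 + 0.2 * X3))
  t <- ifelse(B == 1, tpos, 0)
  lam <- exp(-1 + 0.5 * t + 2 / (1 + exp(-3 * X1)) + 0.2 * X2 -
               0.2 * exp(X3))
  y <- stats::rnbinom(n, size = 1, mu = lam)  # theta = 1
  data.frame(X1 = X1, X2 = X2, X3 = X3, B = B, T = t, Y = y)
}

#' Misspecified (transformed) covariate functionals
#'
#' Returns the transformed covariate set used to study robustness to
#' misspecified functional forms in the propensity model:
#' \eqn{X_1^t = (1 + X_1 + X_2)^2}, \eqn{X_2^t = X_2/\{1+\exp(X_1)\}},
#' \eqn{X_3^t = X_3^3}.  The first and third are highly predictive of the
#' outcome in the benchmark data-generating process.
#'
#' @param x a matrix or data frame containing columns `X1`, `X2`, `X3`.
#' @return A matrix with columns `X1t`, `X2t`, `X3t`.
#' @examples
#' transform_covariates(data.frame(X1 = 0, X2 = 0, X3 = 0))  # (1, 0, 0)
#' @export
transform_covariates <- function(x) {
  x <- as.data.frame(x)
  stopifnot(all(c("X1", "X2", "X3") %in% names(x)))
  cbind(X1t = (1 + x$X1 + x$X2)^2,
        X2t = x$X2 / (1 + exp(x$X1)),
        X3t = x$X3^3)
}

#' Simulate a longitudinal binary-treatment panel
#'
#' A minimal unbalanced-panel generator for exercising the pooled
#' (unit-interval) weight constraints: each unit is observed for
#' \eqn{m_i \sim \mathrm{Uniform}\{1, \dots, m\}} intervals; a time-varying
#' covariate follows the AR(1) process \eqn{X_{ij} = 0.5 X_{i,j-1} +
#' N(0,1)} (started at \eqn{X_{i0} = 0}); the binary treatment has
#' \eqn{\mathrm{logit}\,\mathrm{pr}(T_{ij}=1) = 0.3 + 0.8 X_{ij} +
#' 0.4 T_{i,j-1}} (with \eqn{T_{i0} = 0}).
#'
#' @param n number of units.
#' @param m maximum number of intervals per unit.
#' @param seed integer seed.
#' @param coef_x,coef_tlag dependence coefficients (defaults 0.8, 0.4); set
#'   to 0 for an iid Bernoulli null.
#' @return A long-format `data.frame` with columns `id`, `interval`, `X`,
#'   `treatment`.
#' @export
simulate_longitudinal <- function(n, m, seed = NULL, coef_x = 0.8,
                                  coef_tlag = 0.4) {
  stopifnot(n >= 1, m >= 1)
  if (!is.null(seed)) set.seed(seed)
  mi <- sample.int(m, n, replace = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    xprev <- 0; tprev <- 0
    X <- Tt <- numeric(mi[i])
    for (j in seq_len(mi[i])) {
      X[j] <- 0.5 * xprev + stats::rnorm(1)
      Tt[j] <- stats::rbinom(1, 1, stats::plogis(0.3 + coef_x * X[j] +
                                                   coef_tlag * tprev))
      xprev <- X[j]; tprev <- Tt[j]
    }
    rows[[i]] <- data.frame(id = i, interval = seq_len(mi[i]), X = X,
                            treatment = Tt)
  }
  do.call(rbind, rows)
}
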