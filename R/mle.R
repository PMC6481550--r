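#' Maximum-likelihood fit of the conditional propensity function model
#'
#' Fits \eqn{\mathrm{pr}(T \mid \tilde X; \beta)} for the chosen family by
#' maximum likelihood, optionally with unit weights (used both for the
#' stabilized-weight baseline and for weighted balance refits).  For the
#' normal and semicontinuous families, structure `"A"` lets the
#' log-standard-deviation be a linear function of the design vector, while
#' structure `"B"` restricts it to an intercept.  The two components of the
#' semicontinuous two-part likelihood are separable and fitted separately:
#' logistic regression for the zero/nonzero indicator and a (possibly
#' heteroscedastic) normal model for `g(T)` on the nonzero part.
#'
#' @param t treatment vector.
#' @param x design matrix ([design_matrix()]); covariate matrix and `NULL`
#'   are accepted.
#' @param family a [treatment_family()] (or name).
#' @param weights optional nonnegative unit weights (default all one).
#'
#' @return An object of class `"caew_propensity"`: list with `family`,
#'   `beta` (named coefficient vector(s); for two-part fits a list with
#'   components `binary`, `mean`, `logsd`), `fitted` (per-unit conditional
#'   density parameters), `loglik`, `converged`.
#' @export
fit_conditional <- function(t, x, family, weights = NULL) {
  family <- as_family(family)
  n <- length(t)
  x <- as_design(x, n)
  if (is.null(weights)) weights <- rep(1, n)
  w <- if (inherits(weights, "caew_weights")) weights$w else as.numeric(weights)
  if (length(w) != n || any(w < 0)) {
    stop("'weights' must be nonnegative and of length n", call. = FALSE)
  }
  if (n <= ncol(x)) {
    stop("need more units than propensity model parameters", call. = FALSE)
  }

  out <- switch(family$name,
    binary = {
      if (!all(t %in% c(0, 1))) stop("binary treatment must be coded 0/1",
                                     call. = FALSE)
      f <- fit_logistic(t, x, w)
      list(beta = f$beta, fitted = list(pi = f$p), loglik = f$loglik,
           converged = f$converged)
    },
    categorical = {
      f <- fit_multinomial(t, x, w)
      list(beta = f$beta, fitted = list(probs = f$probs), loglik = f$loglik,
           converged = f$converged)
    },
    normal = {
      f <- fit_hetnormal(t, x, w, structure = family$structure)
      list(beta = list(mean = f$bmu, logsd = f$bsig),
           fitted = list(mu = f$mu, sigma = f$sigma),
           loglik = f$loglik, converged = f$converged)
    },
    poisson = {
      f <- fit_poisson(t, x, w)
      list(beta = f$beta, fitted = list(lambda = f$lambda), loglik = f$loglik,
           converged = f$converged)
    },
    semicontinuous = {
      member <- two_part_member(t)
      fb <- fit_logistic(as.numeric(member), x, w)
      gt <- g_fun(family$g)(t[member])
      fc <- fit_hetnormal(gt, x[member, , drop = FALSE], w[member],
                          structure = family$structure)
      mu <- sigma <- rep(NA_real_, n)
      mu[member] <- fc$mu
      sigma[member] <- fc$sigma
      list(beta = list(binary = fb$beta, mean = fc$bmu, logsd = fc$bsig),
           fitted = list(pi = fb$p, mu = mu, sigma = sigma, member = member),
           loglik = fb$loglik + fc$loglik,
           converged = fb$converged && fc$converged)
    },
    stop("unsupported family: ", family$name, call. = FALSE)
  )
  out$family <- family
  out$design_cols <- colnames(x)
  class(out) <- "caew_propensity"
  out
}

#' @export
print.caew_propensity <- function(x, digits = 4, ...) {
  cat("Conditional propensity model (", x$family$name, ")\n", sep = "")
  cat("  log-likelihood:", format(x$loglik, digits = digits),
      " converged:", x$converged, "\n")
  utils::str(lapply(if (is.list(x$beta)) x$beta else list(beta = x$beta),
                    round, digits), give.attr = FALSE)
  invisible(x)
}

## ---- component fitters (weighted ML) --------------------------------------

fit_logistic <- function(y, x, w) {
  sep_warn <- FALSE
  ## quasibinomial: same IRLS solution, no non-integer-weight warnings
  fit <- withCallingHandlers(
    stats::glm.fit(x, y, weights = w, family = stats::quasibinomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 200)),
    warning = function(wn) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(wn))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- stats::coef(fit)
  p <- as.vector(fit$fitted.values)
  ## perfect classification with diverging coefficients: the ML estimate
  ## does not exist
  pos <- w > 0
  separated <- max(abs(beta), na.rm = TRUE) > 10 &&
    (!any(pos & y == 0) || max(p[pos & y == 0]) < 1e-6) &&
    (!any(pos & y == 1) || min(p[pos & y == 1]) > 1 - 1e-6)
  if (separated) {
    stop("perfect separation in the logistic propensity model", call. = FALSE)
  }
  ll <- sum(w * stats::dbinom(y, 1, p, log = TRUE))
  list(beta = beta, p = p, loglik = ll, converged = fit$converged)
}

fit_poisson <- function(y, x, w) {
  fit <- stats::glm.fit(x, y, weights = w, family = stats::poisson(),
                        control = stats::glm.control(epsilon = 1e-12,
                                                     maxit = 200))
  lam <- as.vector(fit$fitted.values)
  list(beta = stats::coef(fit), lambda = lam,
       loglik = sum(w * stats::dpois(y, lam, log = TRUE)),
       converged = fit$converged)
}

fit_multinomial <- function(y, x, w) {
  f <- factor(y)
  xx <- x[, -1L, drop = FALSE]  # multinom adds its own intercept
  dat <- data.frame(.y = f, xx, check.names = FALSE)
  fit <- nnet::multinom(.y ~ ., data = dat, weights = w, trace = FALSE,
                        reltol = 1e-14, maxit = 1000)
  beta <- stats::coef(fit)
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1,
                                         dimnames = list(levels(f)[2],
                                                         names(beta)))
  pr <- stats::fitted(fit)
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)
  colnames(pr) <- levels(f)
  idx <- cbind(seq_along(y), as.integer(f))
  list(beta = beta, probs = pr, loglik = sum(w * log(pr[idx])),
       converged = fit$convergence == 0)
}

## normal model with log-linear (structure A) or constant (structure B)
## standard deviation, fitted by BFGS plus Newton refinement on the exact
## weighted score
fit_hetnormal <- function(y, x, w, structure = "A") {
  n <- length(y)
  z <- if (identical(structure, "B")) x[, 1L, drop = FALSE] else x
  p <- ncol(x)
  q <- ncol(z)

  nll <- function(par) {
    mu <- as.vector(x %*% par[1:p])
    ls <- as.vector(z %*% par[p + 1:q])
    sum(w * (ls + (y - mu)^2 / (2 * exp(2 * ls))))
  }
  grad <- function(par) {
    mu <- as.vector(x %*% par[1:p])
    ls <- as.vector(z %*% par[p + 1:q])
    r <- y - mu
    s2 <- exp(2 * ls)
    c(-as.vector(crossprod(x, w * r / s2)),
      as.vector(crossprod(z, w * (1 - r^2 / s2))))
  }

  ## start: weighted least squares mean, constant log-sd
  bmu0 <- tryCatch(stats::lm.wfit(x, y, w)$coefficients,
                   error = function(e) rep(0, p))
  bmu0[is.na(bmu0)] <- 0
  r0 <- y - as.vector(x %*% bmu0)
  s0 <- sqrt(sum(w * r0^2) / sum(w))
  par <- c(bmu0, log(max(s0, 1e-6)), rep(0, q - 1L))

  opt <- stats::optim(par, nll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  par <- opt$par
  ## Newton refinement to drive the score toward zero
  for (it in 1:30) {
    g <- grad(par)
    if (max(abs(g)) < 1e-10 * max(1, sum(w))) break
    H <- tryCatch(stats::optimHess(par, nll, grad), error = function(e) NULL)
    step <- if (is.null(H)) NULL else
      tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- par - step
    if (!is.finite(nll(cand)) || nll(cand) > nll(par) + 1e-8) break
    par <- cand
  }
  g <- grad(par)
  converged <- max(abs(g)) < 1e-6 * max(1, sum(w))
  mu <- as.vector(x %*% par[1:p])
  sigma <- exp(as.vector(z %*% par[p + 1:q]))
  list(bmu = stats::setNames(par[1:p], colnames(x)),
       bsig = stats::setNames(par[p + 1:q], colnames(z)),
       mu = mu, sigma = sigma,
       loglik = sum(w * stats::dnorm(y, mu, sigma, log = TRUE)),
       converged = converged)
}

## ---- stabilized weights ----------------------------------------------------

#' Stabilized inverse-probability-of-treatment weights (ML baseline)
#'
#' Computes \eqn{W_i = \mathrm{pr}(T_i;\hat\alpha) / \mathrm{pr}(T_i \mid
#' \tilde X_i;\hat\beta)}, the ratio of the marginal to the conditional
#' treatment density evaluated at the observed treatment (probability mass
#' for discrete components, density for continuous ones; the unit-specific
#' product of the two component ratios for the two-part family), rescaled
#' by its sample mean so the weights sum to `n`.
#'
#' @param marginal a [fit_marginal()] result.
#' @param conditional a [fit_conditional()] result for the same family/data.
#' @param t treatment vector.
#' @param x design matrix (only used for dimension checks).
#'
#' @return A `"caew_weights"` object with `approach = "ml"`.
#' @export
stabilized_weights <- function(marginal, conditional, t, x = NULL) {
  stopifnot(inherits(marginal, "caew_marginal"),
            inherits(conditional, "caew_propensity"))
  if (marginal$family$name != conditional$family$name) {
    stop("marginal and conditional fits use different families", call. = FALSE)
  }
  num <- marginal_density(marginal, t)
  den <- conditional_density(conditional, t)
  if (any(den <= 0 | !is.finite(den))) {
    stop("conditional treatment density is zero at an observed point: ",
         "positivity violation", call. = FALSE)
  }
  w <- num / den
  w <- w / mean(w)
  new_weights(w, system = NULL, status = "optimal", approach = "ml")
}

marginal_density <- function(marginal, t) {
  fam <- marginal$family
  switch(fam$name,
    binary = stats::dbinom(t, 1, marginal$pi0),
    categorical = {
      f <- factor(t, levels = names(marginal$probs))
      as.numeric(marginal$probs[as.integer(f)])
    },
    normal = stats::dnorm(t, marginal$mu0, sqrt(marginal$sigma0_sq)),
    poisson = stats::dpois(t, marginal$lambda0),
    semicontinuous = {
      member <- two_part_member(t)
      out <- ifelse(member, marginal$pi0, 1 - marginal$pi0)
      gt <- g_fun(fam$g)(t[member])
      out[member] <- out[member] *
        stats::dnorm(gt, marginal$mu0, sqrt(marginal$sigma0_sq))
      out
    })
}

conditional_density <- function(fit, t) {
  fam <- fit$family
  switch(fam$name,
    binary = stats::dbinom(t, 1, fit$fitted$pi),
    categorical = {
      f <- factor(t, levels = colnames(fit$fitted$probs))
      fit$fitted$probs[cbind(seq_along(t), as.integer(f))]
    },
    normal = stats::dnorm(t, fit$fitted$mu, fit$fitted$sigma),
    poisson = stats::dpois(t, fit$fitted$lambda),
    semicontinuous = {
      member <- two_part_member(t)
      out <- ifelse(member, fit$fitted$pi, 1 - fit$fitted$pi)
      gt <- g_fun(fam$g)(t[member])
      out[member] <- out[member] *
        stats::dnorm(gt, fit$fitted$mu[member], fit$fitted$sigma[member])
      out
    })
}
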