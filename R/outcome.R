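#' Weighted negative binomial regression of the outcome on treatment
#'
#' Fits the marginal structural outcome model: a negative binomial
#' regression of a count outcome on treatment alone, with the weighted
#' pseudo-population standing in for covariate adjustment.  The
#' parameterization is
#' \deqn{\mathrm{pr}(Y_i = y) = \frac{\Gamma(y + 1/\theta)}{\Gamma(1/\theta)\, y!}
#'   \left(\frac{\theta\lambda_i}{1+\theta\lambda_i}\right)^{y}
#'   \left(\frac{1}{1+\theta\lambda_i}\right)^{1/\theta},}
#' so that \eqn{\mathrm{var}(Y_i) = \lambda_i + \theta \lambda_i^2} and
#' \eqn{\theta \to 0} is the Poisson limit.  The weighted log-likelihood
#' \eqn{\sum_i W_i \log \mathrm{pr}(Y_i)} is maximized jointly over the
#' regression coefficients and \eqn{\log\theta} (BFGS with analytic
#' gradients, plus Newton refinement).  Weights act as frequency-type
#' multipliers; zero-weight units contribute nothing.
#'
#' @param y nonnegative integer outcome vector.
#' @param t treatment vector.
#' @param w weights: a `"caew_weights"` object or numeric vector (default
#'   all one).
#' @param offset optional strictly positive exposure vector `O`; the mean
#'   becomes \eqn{\lambda_i = O_i \exp(\eta_i)}.
#' @param mean_spec functional form of the linear predictor in treatment:
#'   `"linear_in_T"` (\eqn{\gamma_0+\gamma_1 T}), `"indicator_T_positive"`
#'   (\eqn{\gamma_0+\gamma_1 I(T \ne 0)}), `"log1p_T"`
#'   (\eqn{\xi_0+\xi_1\log(T+1)}), or `"indicator_plus_log1p"` (both
#'   nonzero-dose indicator and \eqn{I(T\ne 0)\log(T+1)} terms).
#'
#' @return An object of class `"caew_outcome"`: list with `gamma0`,
#'   `gamma1` (first treatment coefficient — the marginal effect estimand),
#'   `coef` (all regression coefficients), `theta`, `mean_spec`,
#'   `offset_used`, `converged`, `loglik`.
#'
#' @details When the overdispersion estimate runs to the Poisson boundary,
#'   the fit is returned with `theta = 0`, coefficients from the weighted
#'   Poisson regression, and a note via `message()`.
#' @export
fit_weighted_nb <- function(y, t, w = NULL,
                            offset = NULL,
                            mean_spec = c("linear_in_T",
                                          "indicator_T_positive",
                                          "log1p_T",
                                          "indicator_plus_log1p")) {
  mean_spec <- match.arg(mean_spec)
  n <- length(y)
  if (length(t) != n) stop("'y' and 't' lengths differ", call. = FALSE)
  if (any(y < 0) || any(y != round(y))) {
    stop("outcome must be nonnegative integers", call. = FALSE)
  }
  if (all(y == 0)) stop("all outcomes are zero: nothing to fit", call. = FALSE)
  if (is.null(w)) w <- rep(1, n)
  wv <- if (inherits(w, "caew_weights")) w$w else as.numeric(w)
  if (length(wv) != n || any(wv < 0) || anyNA(wv)) {
    stop("weights must be nonnegative, length n", call. = FALSE)
  }
  offset_used <- !is.null(offset)
  if (offset_used && any(offset <= 0)) {
    stop("offsets must be strictly positive", call. = FALSE)
  }
  lo <- if (offset_used) log(offset) else rep(0, n)
  M <- nb_model_matrix(t, mean_spec)
  ## aliased columns (e.g. a constant treatment) are dropped from the fit
  ## and reported as NA coefficients
  qrM <- qr(M)
  aliased <- if (qrM$rank < ncol(M)) {
    setdiff(colnames(M), colnames(M)[qrM$pivot[seq_len(qrM$rank)]])
  } else {
    character(0)
  }
  if (length(aliased)) {
    message("dropping aliased mean-model column(s): ",
            paste(aliased, collapse = ", "))
    kept_cols <- setdiff(colnames(M), aliased)
    M <- M[, kept_cols, drop = FALSE]
  }

  ## zero-weight units contribute exactly nothing
  pos <- wv > 0
  if (!any(pos)) stop("all weights are zero", call. = FALSE)
  Mp <- M[pos, , drop = FALSE]
  yp <- y[pos]; wp <- wv[pos]; lop <- lo[pos]
  p <- ncol(M)

  negll <- function(par) {
    lam <- exp(as.vector(Mp %*% par[1:p]) + lop)
    th <- exp(par[p + 1L])
    -sum(wp * stats::dnbinom(yp, size = 1 / th, mu = lam, log = TRUE))
  }
  gradll <- function(par) {
    lam <- exp(as.vector(Mp %*% par[1:p]) + lop)
    th <- exp(par[p + 1L])
    u <- wp * (yp - lam) / (1 + th * lam)
    dth <- (-1 / th^2) * (digamma(yp + 1 / th) - digamma(1 / th)) +
      yp / th - yp * lam / (1 + th * lam) +
      log1p(th * lam) / th^2 - lam / (th * (1 + th * lam))
    -c(as.vector(crossprod(Mp, u)), th * sum(wp * dth))
  }

  ## start from the weighted Poisson fit
  pois <- stats::glm.fit(Mp, yp, weights = wp, offset = lop,
                         family = stats::poisson(),
                         control = stats::glm.control(epsilon = 1e-12,
                                                      maxit = 200))
  par <- c(stats::coef(pois), 0)
  opt <- stats::optim(par, negll, gradll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  par <- opt$par
  for (it in 1:30) {
    g <- gradll(par)
    if (max(abs(g)) < 1e-9 * max(1, sum(wp))) break
    H <- tryCatch(stats::optimHess(par, negll, gradll),
                  error = function(e) NULL)
    step <- if (is.null(H)) NULL else
      tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- par - step
    if (!is.finite(negll(cand)) || negll(cand) > negll(par) + 1e-8) break
    par <- cand
  }
  theta <- unname(exp(par[p + 1L]))
  coefs <- stats::setNames(par[1:p], colnames(M))
  converged <- opt$convergence == 0

  if (theta < 1e-6) {
    message("overdispersion at the Poisson boundary; returning theta = 0 ",
            "with weighted Poisson coefficients")
    theta <- 0
    coefs <- stats::setNames(stats::coef(pois), colnames(M))
    ll <- sum(wp * stats::dpois(yp, exp(as.vector(Mp %*% coefs) + lop),
                                log = TRUE))
    converged <- pois$converged
  } else {
    ll <- -negll(par)
  }
  if (length(aliased)) {
    full_names <- colnames(nb_model_matrix(t, mean_spec))
    full <- stats::setNames(rep(NA_real_, length(full_names)), full_names)
    full[names(coefs)] <- coefs
    coefs <- full
  }

  out <- list(gamma0 = unname(coefs[1L]), gamma1 = unname(coefs[2L]),
              coef = coefs, theta = theta, mean_spec = mean_spec,
              offset_used = offset_used, converged = converged, loglik = ll)
  class(out) <- "caew_outcome"
  out
}

nb_model_matrix <- function(t, mean_spec) {
  member <- as.numeric(two_part_member(t))
  switch(mean_spec,
    linear_in_T = cbind("(Intercept)" = 1, "T" = t),
    indicator_T_positive = cbind("(Intercept)" = 1, "I(T>0)" = member),
    log1p_T = cbind("(Intercept)" = 1, "log1p(T)" = log1p(t)),
    indicator_plus_log1p = cbind("(Intercept)" = 1, "I(T>0)" = member,
                                 "I(T>0)log1p(T)" = member * log1p(t)))
}

#' @export
print.caew_outcome <- function(x, digits = 4, ...) {
  cat("Weighted negative binomial outcome fit (", x$mean_spec,
      if (x$offset_used) ", with offset", ")\n", sep = "")
  print(round(x$coef, digits))
  cat("  theta =", format(x$theta, digits = digits),
      " loglik =", format(x$loglik, digits = digits),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Serialize an outcome fit to JSON
#' @param x a `"caew_outcome"` object.
#' @param path optional file path.
#' @return JSON string (invisibly when written to file).
#' @export
outcome_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "caew_outcome"))
  js <- jsonlite::toJSON(
    list(coef = as.list(x$coef), theta = x$theta, mean_spec = x$mean_spec,
         offset_used = x$offset_used, converged = x$converged,
         loglik = x$loglik),
    auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Nonparametric bootstrap of the two-stage weighted estimate
#'
#' Resamples units with replacement and redoes the whole pipeline —
#' marginal fit, weight estimation (CAEW or ML), weighted outcome fit — on
#' each resample, returning percentile intervals for the treatment
#' coefficient.  Intended for synthetic experiments; resamples in which the
#' weight problem is infeasible or a fit fails are dropped and counted.
#'
#' @param t,x_tilde,y treatment, covariate matrix (no intercept), outcome.
#' @param family a [treatment_family()].
#' @param approach `"caew"` or `"ml"`.
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @param mean_spec,offset passed to [fit_weighted_nb()].
#' @return list with `estimate`, `ci` (percentile), `boot` (replicate
#'   estimates), `n_failed`.
#' @export
bootstrap_effect <- function(t, x_tilde, y, family, approach = c("caew", "ml"),
                             n_boot = 200, level = 0.95, seed = 1,
                             mean_spec = "linear_in_T", offset = NULL) {
  approach <- match.arg(approach)
  family <- as_family(family)
  n <- length(t)
  est_fun <- function(idx) {
    ti <- t[idx]; xi <- x_tilde[idx, , drop = FALSE]; yi <- y[idx]
    oi <- if (is.null(offset)) NULL else offset[idx]
    w <- estimate_weights(ti, xi, family, approach)
    fit_weighted_nb(yi, ti, w, offset = oi, mean_spec = mean_spec)$gamma1
  }
  point <- est_fun(seq_len(n))
  set.seed(seed)
  reps <- numeric(0)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(suppressWarnings(suppressMessages(est_fun(idx))),
                    error = function(e) NA_real_)
    if (is.na(val)) n_failed <- n_failed + 1L else reps <- c(reps, val)
  }
  alpha <- (1 - level) / 2
  list(estimate = point,
       ci = stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE),
       boot = reps, n_failed = n_failed)
}

#' Estimate weights by either approach
#'
#' Convenience wrapper running the full weight-estimation pipeline:
#' marginal fit, then either the CAEW constraint system solved by quadratic
#' programming, or the ML two-stage stabilized ratio.
#'
#' @inheritParams bootstrap_effect
#' @param projection_override passed to [build_conditions()] (CAEW only).
#' @return A `"caew_weights"` object.
#' @export
estimate_weights <- function(t, x_tilde, family, approach = c("caew", "ml"),
                             projection_override = NULL) {
  approach <- match.arg(approach)
  family <- as_family(family)
  marg <- fit_marginal(t, family)
  if (approach == "caew") {
    cs <- build_conditions(t, design_matrix(x_tilde), family, marg,
                           projection_override)
    solve_weights(cs)
  } else {
    cond <- fit_conditional(t, design_matrix(x_tilde), family)
    stabilized_weights(marg, cond, t)
  }
}
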