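#' Fit the marginal treatment model pr(T; alpha)
#'
#' Maximum-likelihood fit of the covariate-free treatment model for a given
#' family.  Its estimates define the projection function: the treatment
#' distribution imposed on the weighted pseudo-population.  All estimates
#' solve the covariate-free score equations exactly; in particular the
#' variance estimate uses the maximum-likelihood denominator \eqn{n}, not
#' \eqn{n-1}, so that the variance score is exactly zero at the fit.
#'
#' @param t treatment vector.  Binary treatments must be coded 0/1;
#'   categorical treatments may be any atomic type (levels are taken from
#'   `factor(t)`); Poisson treatments are nonnegative counts; semicontinuous
#'   treatments have a point mass at zero and a continuous nonzero part.
#' @param family a [treatment_family()] (or family name).
#'
#' @return An object of class `"caew_marginal"` with components `family`,
#'   `n_fit`, and the family-relevant parameters among `pi0` (probability of
#'   treatment / of a nonzero dose), `probs` (category proportions), `mu0`
#'   and `sigma0_sq` (mean and ML variance of `t`, or of `g(t)` over the
#'   nonzero part), `lambda0` (Poisson mean).
#'
#' @details A degenerate marginal (constant treatment, `pi0` of 0 or 1,
#'   fewer than two distinct values in the continuous part) is an error:
#'   no covariate-association constraint can be anchored to it.
#' @examples
#' fit_marginal(c(1, 0, 1, 0), "binary")
#' fit_marginal(c(0, 0, 1.2, 3.1, 0.7), treatment_family("semicontinuous"))
#' @export
fit_marginal <- function(t, family) {
  family <- as_family(family)
  if (length(t) == 0L) stop("empty treatment vector", call. = FALSE)
  if (anyNA(t)) stop("treatment vector contains NA", call. = FALSE)
  n <- length(t)
  out <- list(family = family, n_fit = n)

  degenerate <- function(msg) {
    stop("degenerate marginal for family '", family$name, "': ", msg,
         call. = FALSE)
  }

  switch(family$name,
    binary = {
      if (!all(t %in% c(0, 1))) stop("binary treatment must be coded 0/1",
                                     call. = FALSE)
      p <- mean(t)
      if (p <= 0 || p >= 1) degenerate("observed treatment proportion is 0 or 1")
      out$pi0 <- p
    },
    categorical = {
      f <- factor(t)
      if (nlevels(f) < 2L) degenerate("fewer than two observed categories")
      out$probs <- as.vector(table(f)) / n
      names(out$probs) <- levels(f)
    },
    normal = {
      mu <- mean(t)
      s2 <- sum((t - mu)^2) / n
      if (s2 <= 0) degenerate("zero variance (all treatment values equal)")
      out$mu0 <- mu
      out$sigma0_sq <- s2
    },
    poisson = {
      if (any(t < 0) || any(t != round(t))) {
        stop("poisson treatment must be nonnegative integers", call. = FALSE)
      }
      lam <- mean(t)
      if (lam <= 0) degenerate("all counts are zero")
      out$lambda0 <- lam
    },
    semicontinuous = {
      member <- two_part_member(t)
      p <- mean(member)
      if (p <= 0 || p >= 1) degenerate("nonzero-dose proportion is 0 or 1")
      pos <- t[member]
      if (length(pos) < 2L) degenerate("fewer than 2 nonzero treatment values")
      gt <- g_fun(family$g)(pos)
      mu <- mean(gt)
      s2 <- sum((gt - mu)^2) / length(gt)
      if (s2 <= 0) degenerate("zero variance of the nonzero part")
      out$pi0 <- p
      out$mu0 <- mu
      out$sigma0_sq <- s2
    },
    stop("unsupported family: ", family$name, call. = FALSE)
  )
  class(out) <- "caew_marginal"
  out
}

#' @export
print.caew_marginal <- function(x, digits = 4, ...) {
  cat("Marginal treatment model (", x$family$name, ", n = ", x$n_fit, ")\n",
      sep = "")
  for (nm in c("pi0", "mu0", "sigma0_sq", "lambda0")) {
    if (!is.null(x[[nm]])) cat("  ", nm, " = ", format(x[[nm]], digits = digits),
                               "\n", sep = "")
  }
  if (!is.null(x$probs)) {
    cat("  probs:\n")
    print(round(x$probs, digits))
  }
  invisible(x)
}

#' Serialize a marginal fit to JSON
#'
#' @param x a `"caew_marginal"` object.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
marginal_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "caew_marginal"))
  obj <- list(family = x$family$name, structure = x$family$structure,
              g = x$family$g, n_fit = x$n_fit)
  for (nm in c("pi0", "mu0", "sigma0_sq", "lambda0", "probs")) {
    if (!is.null(x[[nm]])) obj[[nm]] <- x[[nm]]
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
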