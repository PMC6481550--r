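#' Assess covariate balance by weighted refitting of the propensity model
#'
#' The defining property of covariate-association-eliminating weights is
#' that refitting the chosen propensity function model to the weighted data
#' returns a zero dependence block: every covariate coefficient
#' \eqn{\hat\beta_d(W)} is (numerically) zero, because the weights were
#' constructed to make the marginal fit a root of the weighted score
#' equations.  This function performs that refit — solving the same
#' weighted score equations the constraints were derived from, not a
#' different variance structure — and summarizes weight behaviour.
#'
#' @param t treatment vector.
#' @param x design matrix ([design_matrix()]) or covariate matrix.
#' @param w a `"caew_weights"` object or numeric weight vector.
#' @param family a [treatment_family()] (or name).
#'
#' @return An object of class `"caew_balance"`: list with `beta_d_refit`
#'   (named vector of refitted dependence coefficients, one per covariate
#'   per model component), `max_abs_beta_d`, `ess` (effective sample size
#'   \eqn{(\sum W)^2 / \sum W^2}), `n_zero`, `weight_cv` (coefficient of
#'   variation of the weights), `converged`, `balanced` (at the `1e-4`
#'   elementwise criterion).
#'
#' @details Constant (zero-variance) covariate columns have no identifiable
#'   dependence coefficient; they are excluded with a warning.  A
#'   non-convergent weighted refit is reported (`converged = FALSE`), not
#'   fatal.
#' @export
balance_refit <- function(t, x, w, family) {
  family <- as_family(family)
  n <- length(t)
  x <- as_design(x, n)
  wv <- if (inherits(w, "caew_weights")) w$w else as.numeric(w)
  if (length(wv) != n || any(wv < 0) || anyNA(wv)) {
    stop("weights must be nonnegative, length n", call. = FALSE)
  }

  ## exclude degenerate covariate columns (dependence coefficient undefined)
  covs <- setdiff(colnames(x), "(Intercept)")
  const <- covs[vapply(covs, function(j) stats::var(x[, j]) < 1e-24,
                       logical(1))]
  if (length(const)) {
    warning("excluding constant covariate column(s) from the balance refit: ",
            paste(const, collapse = ", "), call. = FALSE)
    x <- x[, setdiff(colnames(x), const), drop = FALSE]
    class(x) <- c("caew_design", "matrix", "array")
  }

  fit <- tryCatch(fit_conditional(t, x, family, weights = wv),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    beta_d <- NULL
    converged <- FALSE
    warning("weighted refit failed: ", conditionMessage(fit), call. = FALSE)
  } else {
    beta_d <- dependence_block(fit)
    converged <- fit$converged
  }

  out <- list(beta_d_refit = beta_d,
              max_abs_beta_d = if (is.null(beta_d)) NA_real_ else
                max(abs(beta_d)),
              ess = sum(wv)^2 / sum(wv^2),
              n_zero = sum(wv == 0),
              weight_cv = stats::sd(wv) / mean(wv),
              converged = converged)
  out$balanced <- isTRUE(out$max_abs_beta_d <= 1e-4)
  class(out) <- "caew_balance"
  out
}

## covariate (non-intercept) coefficients of every model component
dependence_block <- function(fit) {
  fam <- fit$family
  drop1 <- function(v, prefix) {
    v <- v[setdiff(names(v), "(Intercept)")]
    if (length(v)) stats::setNames(v, paste0(prefix, names(v))) else
      stats::setNames(numeric(0), character(0))
  }
  switch(fam$name,
    binary = drop1(fit$beta, "binary:"),
    poisson = drop1(fit$beta, "poisson:"),
    categorical = {
      bd <- fit$beta[, setdiff(colnames(fit$beta), "(Intercept)"),
                     drop = FALSE]
      stats::setNames(as.vector(bd),
                      as.vector(outer(rownames(bd), colnames(bd),
                                      function(r, c) paste0("cat[", r, "]:", c))))
    },
    normal = c(drop1(fit$beta$mean, "mean:"), drop1(fit$beta$logsd, "logsd:")),
    semicontinuous = c(drop1(fit$beta$binary, "binary:"),
                       drop1(fit$beta$mean, "mean:"),
                       drop1(fit$beta$logsd, "logsd:")))
}

#' @export
print.caew_balance <- function(x, digits = 4, ...) {
  cat("Balance report\n")
  cat("  max |beta_d| after weighting:",
      format(x$max_abs_beta_d, digits = digits),
      if (isTRUE(x$balanced)) "(balanced at 1e-4)" else "", "\n")
  cat("  effective sample size:", format(x$ess, digits = digits),
      "  zero weights:", x$n_zero,
      "  weight CV:", format(x$weight_cv, digits = digits), "\n")
  if (!is.null(x$beta_d_refit) && length(x$beta_d_refit)) {
    print(round(x$beta_d_refit, digits))
  }
  invisible(x)
}

#' Serialize a balance report to JSON
#' @param x a `"caew_balance"` object.
#' @param path optional file path.
#' @return JSON string (invisibly when written to file).
#' @export
balance_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "caew_balance"))
  js <- jsonlite::toJSON(
    list(beta_d_refit = as.list(x$beta_d_refit),
         max_abs_beta_d = x$max_abs_beta_d, ess = x$ess, n_zero = x$n_zero,
         weight_cv = x$weight_cv, balanced = x$balanced,
         converged = x$converged),
    auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
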