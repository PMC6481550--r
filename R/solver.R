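#' Minimum-variance nonnegative weights under the constraint system
#'
#' Solves the strictly convex quadratic program
#' \deqn{\min_W \sum_i (W_i - 1)^2 \quad \text{s.t.}\quad A W = b,\; W_i \ge 0,}
#' whose equality rows are the covariate-association-eliminating score
#' conditions plus the sum-to-n row.  Because the mean of the weights is
#' fixed at one, the objective minimizes the variance of the weights, or
#' equivalently the amount of extrapolation from the observed data in the
#' L2 sense.  Units may receive exactly zero weight; they are reported, not
#' dropped.
#'
#' @param system a `"caew_conditions"` object.
#' @param tol feasibility tolerance at which the solution is declared
#'   optimal (default `1e-8`); residuals up to `1e-6` are still reported as
#'   optimal with a note, larger ones demote the status to `"degenerate"`.
#'
#' @return An object of class `"caew_weights"`: list with the weight vector
#'   `w`, `objective` (`sum((w-1)^2)`), `max_residual`
#'   (\eqn{\|AW-b\|_\infty}), `n_zero` (weights exactly zero), `status`
#'   (`"optimal"` or `"degenerate"`), and `active` (indices at the
#'   nonnegativity bound).
#'
#' @details An empty feasible set raises a structured error of class
#'   `"caew_infeasible"` carrying the most-violated constraint rows
#'   (computed from a nonnegativity-respecting least-squares relaxation);
#'   infeasibility typically signals a near-violation of the positivity
#'   assumption, so that the data carry little information about the
#'   requested balance.  The solver is `quadprog`'s dual active-set method
#'   followed by an exact equality re-solve on the final support (polish).
#' @examples
#' cs <- build_conditions(c(1, 1, 0, 0), cbind(z = c(1, 0, 0, -1)),
#'                        "binary", projection_override = 0.5)
#' solve_weights(cs)$w   # c(0, 2, 2, 0)
#' @export
solve_weights <- function(system, tol = 1e-8) {
  stopifnot(inherits(system, "caew_conditions"))
  A <- system$A
  b <- system$b
  n <- ncol(A)
  K <- nrow(A)

  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = rep(1, n),
                       Amat = cbind(t(A), diag(n)),
                       bvec = c(b, rep(0, n)), meq = K,
                       factorized = TRUE),
    error = function(e) e
  )
  if (inherits(sol, "error")) {
    if (grepl("inconsistent|no solution", conditionMessage(sol))) {
      infeasible_error(system)
    }
    w <- rep(NA_real_, n)
    warning("quadratic program failed numerically: ", conditionMessage(sol),
            call. = FALSE)
    return(new_weights(w, system, status = "degenerate"))
  }

  w <- sol$solution
  w[w < 0 & w > -1e-9] <- 0
  w <- polish_weights(w, A, b)
  res <- max(abs(A %*% w - b))
  status <- if (res <= 1e-6) "optimal" else "degenerate"
  if (status == "degenerate") {
    warning("constraint residual ", format(res),
            " exceeds the reporting tolerance 1e-6", call. = FALSE)
  } else if (res > tol) {
    message("constraint residual ", format(res),
            " above the declaration tolerance ", format(tol),
            " but within 1e-6")
  }
  if (any(w < 0)) {
    status <- "degenerate"
    warning("negative weights returned by the solver", call. = FALSE)
  }
  new_weights(w, system, status = status)
}

## exact equality re-solve on the support of the active-set solution; keeps
## the original solution if the refinement is not an improvement
polish_weights <- function(w, A, b) {
  S <- w > 1e-10
  if (!any(S)) return(w)
  As <- A[, S, drop = FALSE]
  wp <- tryCatch({
    ## minimum-norm multipliers via the pseudoinverse: the support may not
    ## span all constraint rows
    M <- tcrossprod(As)
    sv <- svd(M)
    pos <- sv$d > 1e-12 * max(sv$d, 1e-300)
    r <- as.vector(b - As %*% rep(1, sum(S)))
    lam <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], r)) / sv$d[pos])
    as.vector(1 + crossprod(As, lam))
  }, error = function(e) NULL)
  if (is.null(wp) || any(wp < 0)) return(w)
  w2 <- numeric(length(w))
  w2[S] <- wp
  if (max(abs(A %*% w2 - b)) <= max(max(abs(A %*% w - b)), 1e-12)) w2 else w
}

#' Closed-form minimizer ignoring the nonnegativity bounds
#'
#' Returns the equality-constrained least-squares solution
#' \eqn{W = 1 + A^T (A A^T)^{-1} (b - A 1)}, the unique minimizer of
#' `sum((W-1)^2)` subject to `A %*% W = b` only.  It coincides with
#' [solve_weights()] whenever it is elementwise nonnegative, and serves as
#' an oracle and as a detector of active nonnegativity constraints.
#'
#' @inheritParams solve_weights
#' @return A `"caew_weights"` object (entries may be negative).
#' @export
equality_only_solution <- function(system) {
  stopifnot(inherits(system, "caew_conditions"))
  A <- system$A
  b <- system$b
  n <- ncol(A)
  M <- tcrossprod(A)
  lam <- tryCatch(solve(M, b - A %*% rep(1, n)), error = function(e) {
    stop("A %*% t(A) is singular; deduplicate the constraint rows first",
         call. = FALSE)
  })
  w <- as.vector(1 + crossprod(A, lam))
  new_weights(w, system, status = "optimal")
}

new_weights <- function(w, system = NULL, status, approach = "caew") {
  res <- if (!is.null(system) && !anyNA(w)) {
    max(abs(system$A %*% w - system$b))
  } else {
    NA_real_
  }
  out <- list(w = w,
              objective = if (anyNA(w)) NA_real_ else sum((w - 1)^2),
              max_residual = res,
              n_zero = if (anyNA(w)) NA_integer_ else sum(w == 0),
              active = if (anyNA(w)) integer(0) else which(w == 0),
              status = status,
              approach = approach)
  class(out) <- "caew_weights"
  out
}

#' @export
print.caew_weights <- function(x, digits = 4, ...) {
  cat("Weights (", x$approach, "): n = ", length(x$w),
      ", status = ", x$status, "\n", sep = "")
  cat("  objective sum((w-1)^2) = ", format(x$objective, digits = digits),
      ", zero weights = ", x$n_zero, "\n", sep = "")
  if (!is.na(x$max_residual)) {
    cat("  max constraint residual = ",
        format(x$max_residual, digits = digits), "\n", sep = "")
  }
  invisible(x)
}

## structured infeasibility error with the most-violated rows
infeasible_error <- function(system) {
  viol <- tryCatch(most_violated_rows(system), error = function(e) NULL)
  msg <- paste0(
    "constraint system is infeasible: no nonnegative weights satisfy the ",
    "balance conditions.\nThis usually reflects a (near-)violation of the ",
    "positivity assumption: some covariate patterns carry almost no ",
    "information about parts of the treatment distribution."
  )
  if (!is.null(viol)) {
    msg <- paste0(msg, "\nMost-violated rows (best nonnegative fit): ",
                  paste0(viol$label, " (", format(viol$residual, digits = 3),
                         ")", collapse = ", "))
  }
  cond <- structure(
    class = c("caew_infeasible", "error", "condition"),
    list(message = msg, call = NULL, most_violated = viol)
  )
  stop(cond)
}

## best nonnegative least-squares fit to the constraints (ridge-regularized
## toward W = 1), used only to describe which rows cannot be met
most_violated_rows <- function(system) {
  A <- system$A
  b <- system$b
  n <- ncol(A)
  eps <- 1e-6 * max(1, max(abs(A))^2)
  D <- 2 * (crossprod(A) + diag(eps, n))
  d <- 2 * (as.vector(crossprod(A, b)) + eps)
  sol <- quadprog::solve.QP(D, d, diag(n), rep(0, n), meq = 0)
  r <- as.vector(A %*% sol$solution - b)
  rn <- abs(r) / pmax(sqrt(rowSums(A^2)), 1)
  ord <- order(rn, decreasing = TRUE)
  top <- ord[seq_len(min(5L, length(ord)))]
  data.frame(label = system$row_labels[top], residual = r[top],
             stringsAsFactors = FALSE)
}

#' Write or read a weight vector as CSV
#'
#' @param w a `"caew_weights"` object (or bare numeric vector).
#' @param path file path.
#' @param id optional unit identifiers (default `seq_along(w)`).
#' @return `write_weights` invisibly returns `path`; `read_weights` returns
#'   a numeric vector named by unit id.
#' @export
write_weights <- function(w, path, id = NULL) {
  wv <- if (inherits(w, "caew_weights")) w$w else as.numeric(w)
  if (is.null(id)) id <- seq_along(wv)
  utils::write.csv(data.frame(id = id, weight = wv), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path)
  stats::setNames(df$weight, df$id)
}
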