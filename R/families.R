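#' Specify a treatment family for the propensity function model
#'
#' A treatment family describes the distributional form assumed for the
#' treatment variable in the propensity function model
#' \eqn{\mathrm{pr}(T \mid \tilde X; \beta)}.  The family determines which
#' score equations are inverted to obtain the weight constraints, which
#' marginal model parameterizes the projection function, and how the
#' maximum-likelihood baseline weights are computed.
#'
#' @param name one of `"binary"`, `"categorical"`, `"normal"`, `"poisson"`,
#'   `"semicontinuous"`.  `"normal_heteroscedastic"` is accepted as an alias
#'   for `name = "normal", structure = "A"`.
#' @param structure model structure for the (conditional) variance of a
#'   normal or semicontinuous-positive-part treatment: `"A"` lets the
#'   log-standard-deviation depend on covariates, `"B"` restricts it to a
#'   constant.  Ignored for binary, categorical and Poisson families.
#' @param g monotone transform applied to the nonzero part of a
#'   semicontinuous treatment before the normal model is applied:
#'   `"identity"` or `"log1p"` (i.e. \eqn{g(x)=\log(x+1)}, useful to reduce
#'   right skewness of positive doses).  Ignored for other families.
#'
#' @return An object of class `"caew_family"`.
#' @examples
#' treatment_family("semicontinuous", structure = "A", g = "log1p")
#' @export
treatment_family <- function(name = c("binary", "categorical", "normal",
                                      "normal_heteroscedastic", "poisson",
                                      "semicontinuous"),
                             structure = c("A", "B"),
                             g = c("identity", "log1p")) {
  name <- match.arg(name)
  structure <- match.arg(structure)
  g <- match.arg(g)
  if (name == "normal_heteroscedastic") {
    name <- "normal"
    structure <- "A"
  }
  if (!name %in% c("normal", "semicontinuous")) structure <- NA_character_
  if (name != "semicontinuous") g <- NA_character_
  structure(list(name = name, structure = structure, g = g),
            class = "caew_family")
}

#' @export
print.caew_family <- function(x, ...) {
  cat("Treatment family:", x$name)
  if (!is.na(x$structure)) cat(" (structure ", x$structure, ")", sep = "")
  if (!is.na(x$g)) cat(", g =", x$g)
  cat("\n")
  invisible(x)
}

as_family <- function(family) {
  if (inherits(family, "caew_family")) return(family)
  if (is.character(family) && length(family) == 1L) return(treatment_family(family))
  stop("'family' must be a caew_family object or a family name", call. = FALSE)
}

## transform of the nonzero part of a semicontinuous treatment
g_fun <- function(g) {
  switch(g,
         identity = identity,
         log1p = function(x) {
           if (any(x <= -1)) {
             stop("g = 'log1p' requires treatment values > -1", call. = FALSE)
           }
           log1p(x)
         },
         stop("unknown g transform: ", g, call. = FALSE))
}

## membership in the continuous component of a two-part treatment: exact
## zeros form the point mass, every nonzero value belongs to the continuous
## part (identical to T > 0 for nonnegative doses).
two_part_member <- function(t) t != 0

#' Build a design matrix with a prepended intercept column
#'
#' Covariate functionals \eqn{\tilde X_i} enter every propensity function
#' model through the design vector \eqn{X^*_i = (1, \tilde X_i^T)^T}.  This
#' helper assembles the \eqn{n \times (p+1)} matrix of such vectors.
#'
#' @param x a numeric matrix or data frame of covariate functionals
#'   (\eqn{\tilde X}), one row per unit, without an intercept; or `NULL` for
#'   an intercept-only design.
#' @param n number of rows, required only when `x` is `NULL`.
#'
#' @return A numeric matrix of class `"caew_design"` whose first column is
#'   `(Intercept)` (all ones).  Column names are taken from `x` (defaults
#'   `X1, X2, ...`).
#' @examples
#' design_matrix(cbind(age = c(40, 52, 61)))
#' @export
design_matrix <- function(x = NULL, n = NULL) {
  if (is.null(x)) {
    if (is.null(n)) stop("'n' is required when 'x' is NULL", call. = FALSE)
    out <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
    class(out) <- c("caew_design", class(out))
    return(out)
  }
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("covariates must be numeric", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) {
    stop("duplicated covariate column names", call. = FALSE)
  }
  if ("(Intercept)" %in% colnames(x)) {
    stop("'x' must not already contain an intercept column", call. = FALSE)
  }
  out <- cbind("(Intercept)" = 1, x)
  class(out) <- c("caew_design", class(out))
  out
}

as_design <- function(x, n) {
  ## subsetting drops the S3 class; recognize an intercept-first matrix
  if (inherits(x, "caew_design") ||
      (is.matrix(x) && !is.null(colnames(x)) &&
       colnames(x)[1L] == "(Intercept)" && all(x[, 1L] == 1))) {
    if (nrow(x) != n) stop("design matrix has ", nrow(x), " rows; expected ",
                           n, call. = FALSE)
    if (!inherits(x, "caew_design")) {
      class(x) <- c("caew_design", class(x))
    }
    return(x)
  }
  if (is.null(x)) return(design_matrix(NULL, n = n))
  x <- design_matrix(x)
  if (nrow(x) != n) stop("design matrix has ", nrow(x), " rows; expected ",
                         n, call. = FALSE)
  x
}
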