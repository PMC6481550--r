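# Independent oracles and random-instance generators used across the suite.

# Brute-force solver for min sum((w-1)^2) s.t. A w = b, w >= 0 by
# enumerating active sets of the nonnegativity constraints: for every
# subset Z of units forced to zero, solve the equality-constrained problem
# on the complement in closed form, keep feasible candidates, return the
# best.  Exponential in n; only for tiny instances.  Independent of the
# quadprog-based implementation.
brute_force_qp <- function(A, b, tol = 1e-8) {
  n <- ncol(A)
  stopifnot(n <= 14)
  pinv_solve <- function(M, r) {
    sv <- svd(M)
    pos <- sv$d > 1e-10 * max(sv$d, 1e-300)
    sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], r) / sv$d[pos])
  }
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    zero <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0)
    free <- setdiff(seq_len(n), zero)
    if (!length(free)) next
    Af <- A[, free, drop = FALSE]
    lam <- pinv_solve(tcrossprod(Af), b - Af %*% rep(1, length(free)))
    w <- numeric(n)
    w[free] <- 1 + as.vector(crossprod(Af, lam))
    if (any(w[free] < -tol)) next
    if (max(abs(A %*% pmax(w, 0) - b)) > 1e-6) next
    w <- pmax(w, 0)
    obj <- sum((w - 1)^2)
    if (is.null(best) || obj < best$objective - 1e-12) {
      best <- list(w = w, objective = obj)
    }
  }
  best
}

# Random feasible balance instances, one per treatment family, n units.
# Dependence on two standard-normal covariates is kept mild so that the
# nonnegative weight problem stays feasible at n = 200.
random_instance <- function(family_name, structure = "A", n = 200,
                            seed = 1) {
  set.seed(seed)
  x <- cbind(z1 = stats::rnorm(n), z2 = stats::rnorm(n))
  t <- switch(family_name,
    binary = stats::rbinom(n, 1, stats::plogis(0.3 + 0.5 * x[, 1] -
                                                 0.4 * x[, 2])),
    categorical = {
      eta2 <- 0.4 * x[, 1]
      eta3 <- -0.3 * x[, 2]
      p <- cbind(1, exp(eta2), exp(eta3))
      p <- p / rowSums(p)
      apply(p, 1L, function(pr) sample(c("a", "b", "c"), 1L, prob = pr))
    },
    normal = stats::rnorm(n, 0.2 + 0.4 * x[, 1] - 0.3 * x[, 2],
                          exp(0.1 + 0.15 * x[, 1])),
    poisson = stats::rpois(n, exp(0.4 + 0.3 * x[, 1] - 0.2 * x[, 2])),
    semicontinuous = {
      B <- stats::rbinom(n, 1, stats::plogis(0.3 + 0.6 * x[, 1] +
                                               0.4 * x[, 2]))
      pos <- stats::rnorm(n, 1 + 0.4 * x[, 1], exp(0.2 + 0.2 * x[, 2]))
      ifelse(B == 1, pos, 0)
    },
    stop("unknown family"))
  fam <- treatment_family(family_name, structure = structure, g = "identity")
  list(t = t, x = x, family = fam)
}

family_grid <- data.frame(
  family = c("binary", "categorical", "normal", "normal", "poisson",
             "semicontinuous", "semicontinuous"),
  structure = c("A", "A", "A", "B", "A", "A", "B"),
  stringsAsFactors = FALSE)

# Random feasible directions from the solution w: stay in the null space of
# A, keep zero-weight units at zero, and scale so positivity is preserved.
feasible_perturbations <- function(w, A, k = 20, seed = 1) {
  n <- length(w)
  act <- which(w <= 1e-10)
  aug <- rbind(A, diag(n)[act, , drop = FALSE])
  sv <- svd(aug, nv = n)
  r <- sum(sv$d > 1e-10 * max(sv$d))
  if (r >= n) return(list())
  NS <- sv$v[, (r + 1):n, drop = FALSE]
  set.seed(seed)
  out <- vector("list", k)
  sup <- w > 1e-10
  for (i in seq_len(k)) {
    d <- as.vector(NS %*% rnorm(ncol(NS)))
    d[act] <- 0  # exact zeros, not 1e-16 numerical residue
    alpha <- 0.4 * min(w[sup]) / max(abs(d[sup]), 1e-12)
    out[[i]] <- w + alpha * d
  }
  out
}

# weighted negative-binomial log-likelihood in the theta parameterization
# Var = lambda + theta lambda^2, for black-box oracle fits
nb_wll <- function(par, y, M, w, lo) {
  p <- ncol(M)
  lam <- exp(as.vector(M %*% par[1:p]) + lo)
  sum(w * stats::dnbinom(y, size = 1 / exp(par[p + 1]), mu = lam,
                         log = TRUE))
}
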