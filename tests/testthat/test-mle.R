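test_that("saturated logistic fit reproduces group proportions", {
  t <- c(1, 1, 0, 1, 0, 0)
  x <- design_matrix(cbind(z = c(1, 1, 1, 0, 0, 0)))
  fit <- fit_conditional(t, x, "binary")
  expect_equal(unname(fit$fitted$pi), c(2, 2, 2, 1, 1, 1) / 3,
               tolerance = 1e-8)
})

test_that("normal fit with an uninformative covariate reduces to the marginal", {
  set.seed(19)
  t <- rnorm(40, 2, 1.3)
  x <- design_matrix(cbind(z = rep(0, 40)))
  fit <- suppressWarnings(fit_conditional(t, x, treatment_family("normal", "B")))
  m <- fit_marginal(t, "normal")
  expect_equal(unname(fit$beta$mean[1]), m$mu0, tolerance = 1e-6)
  expect_equal(unname(exp(2 * fit$beta$logsd[1])), m$sigma0_sq,
               tolerance = 1e-6)
})

test_that("two-part fit matches a generic black-box maximizer", {
  set.seed(23)
  n <- 10
  x <- design_matrix(cbind(z = rnorm(n)))
  t <- c(0, 0, 0, 1.2, 0.4, 2.5, 0.9, 3.1, 1.7, 0.6)
  fam <- treatment_family("semicontinuous", structure = "A", g = "identity")
  fit <- fit_conditional(t, x, fam)

  member <- as.numeric(t != 0)
  nll <- function(par) {
    pi <- plogis(as.vector(x %*% par[1:2]))
    mu <- as.vector(x %*% par[3:4])
    sig <- exp(as.vector(x %*% par[5:6]))
    -sum(log(ifelse(member == 1, pi * dnorm(t, mu, sig), 1 - pi)))
  }
  bb <- optim(rep(0.1, 6), nll, method = "BFGS",
              control = list(maxit = 10000, reltol = 1e-15))
  got <- c(fit$beta$binary, fit$beta$mean, fit$beta$logsd)
  expect_equal(unname(got), bb$par, tolerance = 1e-3)
  expect_equal(fit$loglik, -bb$value, tolerance = 1e-6)
  # and the fitted likelihood is at least as high as the black box found
  expect_gte(fit$loglik, -bb$value - 1e-8)
})

test_that("perfect separation is an explicit error", {
  t <- c(0, 0, 0, 1, 1, 1)
  x <- design_matrix(cbind(z = c(-3, -2, -1, 1, 2, 3)))
  expect_error(fit_conditional(t, x, "binary"), "separation")
})

test_that("stabilized weights match the closed-form saturated toy", {
  # units ordered (T, X) = (1,1), (1,1), (0,1), (1,0), (0,0), (0,0):
  # pi0 = 1/2, pi(X=1) = 2/3, pi(X=0) = 1/3
  t <- c(1, 1, 0, 1, 0, 0)
  x <- design_matrix(cbind(z = c(1, 1, 1, 0, 0, 0)))
  w <- stabilized_weights(fit_marginal(t, "binary"),
                          fit_conditional(t, x, "binary"), t)
  expect_equal(w$w, c(0.75, 0.75, 1.5, 1.5, 0.75, 0.75), tolerance = 1e-7)
  expect_equal(mean(w$w), 1)
})

test_that("uninformative covariates give unit stabilized weights", {
  set.seed(31)
  t <- rbinom(30, 1, 0.4)
  x <- design_matrix(cbind(z = rep(0, 30)))
  w <- stabilized_weights(fit_marginal(t, "binary"),
                          fit_conditional(t, x, "binary"), t)
  expect_equal(w$w, rep(1, 30), tolerance = 1e-8)
})

test_that("two-part weights factor into component ratios", {
  inst <- random_instance("semicontinuous", "A", n = 80, seed = 41)
  fam <- inst$family
  x <- design_matrix(inst$x)
  marg <- fit_marginal(inst$t, fam)
  cond <- fit_conditional(inst$t, x, fam)
  w <- stabilized_weights(marg, cond, inst$t)

  member <- inst$t != 0
  wb <- ifelse(member, marg$pi0 / cond$fitted$pi,
               (1 - marg$pi0) / (1 - cond$fitted$pi))
  wc <- rep(1, 80)
  wc[member] <- dnorm(inst$t[member], marg$mu0, sqrt(marg$sigma0_sq)) /
    dnorm(inst$t[member], cond$fitted$mu[member], cond$fitted$sigma[member])
  prod <- wb * wc
  expect_equal(w$w, prod / mean(prod), tolerance = 1e-10)
  expect_equal(mean(w$w), 1, tolerance = 1e-12)
})

test_that("ML-weight constraint residuals are consistent with zero at n = 4000", {
  # under the correctly specified model the weighted score sums are
  # mean-zero noise; each scaled row residual should sit within 10 standard
  # errors of zero
  d <- simulate_cross_sectional(4000, seed = 202)
  fam <- treatment_family("semicontinuous", structure = "A", g = "identity")
  x <- as.matrix(d[c("X1", "X2", "X3")])
  marg <- fit_marginal(d$T, fam)
  cond <- fit_conditional(d$T, design_matrix(x), fam)
  w <- stabilized_weights(marg, cond, d$T)
  cs <- build_conditions(d$T, design_matrix(x), fam, marg)
  contrib <- sweep(cs$A, 2L, w$w, `*`)  # per-unit weighted score terms
  r <- abs(rowSums(contrib)) / 4000
  se <- apply(contrib, 1L, sd) / sqrt(4000)
  keep <- cs$row_labels != "sum"
  expect_true(all(r[keep] <= 10 * se[keep]))
})
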