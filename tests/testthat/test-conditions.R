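test_that("already-balanced binary design is satisfied at unit weights", {
  t <- c(1, 0, 1, 0)
  x <- design_matrix(cbind(z = c(1, 1, -1, -1)))
  cs <- build_conditions(t, x, "binary")
  expect_equal(as.vector(cs$A %*% rep(1, 4)), cs$b)
  expect_equal(cs$b, c(0, 0, 4))
})

test_that("intercept score rows vanish at unit weights for every family", {
  # alpha-hat solves the marginal score equations, so the intercept rows of
  # the constraint block are exactly zero at W = 1
  for (i in seq_len(nrow(family_grid))) {
    inst <- random_instance(family_grid$family[i], family_grid$structure[i],
                            n = 80, seed = 100 + i)
    cs <- build_conditions(inst$t, design_matrix(inst$x), inst$family)
    r <- as.vector(cs$A %*% rep(1, 80) - cs$b)
    icpt <- grep("\\(Intercept\\)$|^sum$", cs$row_labels)
    expect_lt(max(abs(r[icpt])), 1e-8)
  }
})

test_that("identically-zero rows are dropped with a warning", {
  t <- c(-1, 1)
  expect_warning(
    cs <- build_conditions(t, design_matrix(cbind(z = c(0, 0))), "normal"),
    "identically-zero")
  # intercept mean and variance rows survive and hold at W = 1
  expect_equal(as.vector(cs$A %*% c(1, 1)), cs$b)
  expect_false(any(grepl(":z$", cs$row_labels)))
})

test_that("constant treatment with every dose nonzero is caught upstream", {
  t <- c(1.2, 2.3, 0.8, 1.7)
  expect_error(fit_marginal(t, "semicontinuous"), "proportion is 0 or 1")
  # with an override the binary-part rows are retained
  m <- suppressWarnings(fit_marginal(c(0, t), "semicontinuous"))
  cs <- build_conditions(c(0, t), design_matrix(cbind(z = c(0, 1, -1, 2, -2))),
                         "semicontinuous", marginal = m,
                         projection_override = 0.5)
  expect_true(any(grepl("^binary:", cs$row_labels)))
})

test_that("rescaling rows leaves the solved weights unchanged", {
  inst <- random_instance("normal", "A", n = 60, seed = 5)
  cs <- build_conditions(inst$t, design_matrix(inst$x), inst$family)
  w1 <- solve_weights(cs)
  cs2 <- cs
  sc <- c(rep(7.3, nrow(cs2$A) - 1L), 1)
  cs2$A <- cs2$A * sc
  cs2$b <- cs2$b * sc
  w2 <- solve_weights(cs2)
  expect_lt(max(abs(w1$w - w2$w)), 1e-7)
})

test_that("semicontinuous rows stack binary-indicator and masked normal rows", {
  inst <- random_instance("semicontinuous", "A", n = 50, seed = 9)
  fam <- inst$family
  x <- design_matrix(inst$x)
  cs <- build_conditions(inst$t, x, fam)
  member <- inst$t != 0
  mb <- fit_marginal(as.numeric(member), "binary")
  csb <- build_conditions(as.numeric(member), x, "binary", mb)
  K <- nrow(csb$A)
  bin_rows <- grep("^binary:", cs$row_labels)
  expect_equal(unname(cs$A[bin_rows, ]), unname(csb$A[-K, , drop = FALSE]))
  # masked normal rows: zero contribution for zero-dose units
  cont_rows <- grep("^(mean|var):", cs$row_labels)
  expect_true(all(cs$A[cont_rows, !member] == 0))
  mn <- fit_marginal(inst$t[member], "normal")
  csn <- build_conditions(inst$t[member], x[member, , drop = FALSE],
                          treatment_family("normal", "A"), mn)
  Kn <- nrow(csn$A)
  expect_equal(unname(cs$A[cont_rows, member]),
               unname(csn$A[-Kn, , drop = FALSE]))
})

test_that("marginal/family and dimension mismatches error", {
  m <- fit_marginal(c(1, 0, 1), "binary")
  expect_error(build_conditions(c(1.2, 0.4, 1), design_matrix(NULL, 3),
                                "normal", m), "family")
  expect_error(build_conditions(c(1, 0, 1), design_matrix(cbind(z = 1:4)),
                                "binary"), "rows")
  expect_error(build_conditions(c(1, 0, 1), design_matrix(NULL, 3), "poisson",
                                projection_override = 0.3), "binary")
})

test_that("single-interval panels reduce to the cross-sectional system", {
  set.seed(11)
  pan <- data.frame(id = 1:40, interval = 1, X = rnorm(40),
                    treatment = rbinom(40, 1, 0.5))
  csl <- pool_longitudinal(pan, "binary")
  csx <- build_conditions(pan$treatment, design_matrix(cbind(X = pan$X)),
                          "binary")
  expect_equal(unname(csl$A), unname(csx$A))
  expect_equal(csl$b, csx$b)
})

test_that("balanced two-unit panel is feasible at unit weights", {
  pan <- data.frame(id = rep(1:2, each = 2), interval = rep(1:2, 2),
                    X = c(1, 1, -1, -1), treatment = c(1, 0, 0, 1))
  cs <- pool_longitudinal(pan, "binary")
  expect_equal(cs$projection$pi0, 0.5)
  expect_equal(as.vector(cs$A %*% rep(1, 4)), cs$b)
  w <- solve_weights(cs)
  expect_equal(w$w, rep(1, 4))
})

test_that("unbalanced pooled weights match the brute-force oracle", {
  # 3 units, m_i = (1, 2, 3): six decision variables, small enough to
  # enumerate every active set
  pan <- data.frame(id = c(1, 2, 2, 3, 3, 3),
                    interval = c(1, 1, 2, 1, 2, 3),
                    X = c(0.9, 0.3, -0.4, 0.8, -0.6, 0.1),
                    treatment = c(1, 0, 1, 0, 0, 1))
  cs <- pool_longitudinal(pan, "binary")
  expect_equal(cs$b[length(cs$b)], 6)  # sum over unit-intervals
  w <- solve_weights(cs)
  oracle <- brute_force_qp(cs$A, cs$b)
  expect_equal(w$objective, oracle$objective, tolerance = 1e-7)
  expect_lt(max(abs(w$w - oracle$w)), 1e-6)
})

test_that("inconsistent panel pieces and empty panels error", {
  p1 <- data.frame(id = 1, interval = 1, X = 0.2, treatment = 1)
  p2 <- data.frame(id = 2, interval = 1, Z = 0.2, treatment = 0)
  expect_error(pool_longitudinal(list(p1, p2), "binary"), "inconsistent")
  expect_error(pool_longitudinal(data.frame(), "binary"), "empty")
})

test_that("self-targeting keeps unit weights feasible", {
  t <- c(1, 0, 1, 0)
  x <- design_matrix(cbind(z = c(1, 1, -1, -1)))
  cs <- append_target_population(build_conditions(t, x, "binary"), c(z = 0))
  expect_equal(as.vector(cs$A %*% rep(1, 4)), cs$b)
})

test_that("target-population rows force the weighted covariate mean", {
  t <- c(1, 1, 0, 0)
  x <- design_matrix(cbind(z = c(1, 0, 0, -1)))
  cs0 <- build_conditions(t, x, "binary", projection_override = 0.5)
  cs <- append_target_population(cs0, c(z = 0))
  w <- solve_weights(cs)
  expect_lt(abs(sum(w$w * c(1, 0, 0, -1))), 1e-8)
  oracle <- brute_force_qp(cs$A, cs$b)
  expect_equal(w$objective, oracle$objective, tolerance = 1e-7)
  expect_error(append_target_population(cs0, c(0, 0)), "length")
})

test_that("targets far outside the covariate hull are infeasible", {
  inst <- random_instance("binary", n = 40, seed = 21)
  cs <- append_target_population(
    build_conditions(inst$t, design_matrix(inst$x), "binary"),
    c(z1 = 50, z2 = 0))
  expect_error(solve_weights(cs), class = "caew_infeasible")
})
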