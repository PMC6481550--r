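test_that("the 4-unit worked instance matches the brute-force oracle", {
  t <- c(1, 1, 0, 0)
  x <- design_matrix(cbind(z = c(1, 0, 0, -1)))
  cs <- build_conditions(t, x, "binary", projection_override = 0.5)
  w <- solve_weights(cs)
  expect_equal(w$w, c(0, 2, 2, 0))
  expect_equal(w$objective, 4)
  expect_equal(w$n_zero, 2L)
  expect_equal(sort(w$active), c(1L, 4L))
  oracle <- brute_force_qp(cs$A, cs$b)
  expect_equal(oracle$objective, 4, tolerance = 1e-8)
  expect_equal(oracle$w, c(0, 2, 2, 0), tolerance = 1e-7)
  # for this instance the sign-unconstrained minimizer already sits on the
  # boundary of the nonnegative cone, so the two solutions coincide
  eo <- equality_only_solution(cs)
  expect_equal(eo$w, c(0, 2, 2, 0), tolerance = 1e-10)
  expect_equal(eo$objective, 4, tolerance = 1e-10)
})

test_that("feasible-at-unit-weights systems return exact unit weights", {
  cs <- build_conditions(c(1, 0, 1, 0),
                         design_matrix(cbind(z = c(1, 1, -1, -1))), "binary")
  w <- solve_weights(cs)
  expect_equal(w$w, rep(1, 4))
  expect_equal(w$objective, 0)
  eo <- equality_only_solution(cs)
  expect_equal(eo$w, rep(1, 4))
})

test_that("a lone sum row gives unit weights", {
  # minimum-norm deviation from 1 subject to sum only
  cs <- build_conditions(c(1, 0, 1), design_matrix(NULL, 3), "binary")
  # drop the binary intercept row, keep the sum row
  cs$A <- cs$A[2, , drop = FALSE]
  cs$b <- cs$b[2]
  cs$row_labels <- "sum"
  expect_equal(equality_only_solution(cs)$w, rep(1, 3))
})

test_that("solver equals the closed form whenever it is nonnegative", {
  hits <- 0L
  for (i in seq_len(nrow(family_grid))) {
    inst <- random_instance(family_grid$family[i], family_grid$structure[i],
                            n = 120, seed = 300 + i)
    cs <- build_conditions(inst$t, design_matrix(inst$x), inst$family)
    eo <- equality_only_solution(cs)
    w <- solve_weights(cs)
    if (all(eo$w >= 0)) {
      hits <- hits + 1L
      expect_lt(max(abs(w$w - eo$w)), 1e-8)
    } else {
      # constrained optimum cannot beat the unconstrained-in-sign optimum
      expect_gte(w$objective, eo$objective - 1e-8)
    }
    expect_lt(w$max_residual, 1e-6)
  }
  expect_gt(hits, 0L)  # the closed form must be exercised at least once
})

test_that("solutions are optimal against feasible perturbations", {
  inst <- random_instance("normal", "B", n = 60, seed = 13)
  cs <- build_conditions(inst$t, design_matrix(inst$x), inst$family)
  w <- solve_weights(cs)
  perts <- feasible_perturbations(w$w, cs$A, k = 25, seed = 77)
  expect_gt(length(perts), 0L)
  for (wp in perts) {
    expect_lt(max(abs(cs$A %*% wp - cs$b)), 1e-8)  # still feasible
    expect_true(all(wp >= 0))
    expect_gte(sum((wp - 1)^2), w$objective - 1e-8)
  }
})

test_that("random small instances match the brute-force oracle", {
  set.seed(5150)
  for (k in 1:10) {
    n <- 8
    A <- rbind(matrix(rnorm(2 * n), 2, n), rep(1, n))
    b <- c(rnorm(2, 0, 0.4), n)
    cs <- structure(list(A = A, b = b,
                         row_labels = c("r1", "r2", "sum"),
                         family = treatment_family("binary"),
                         n_units = n),
                    class = "caew_conditions")
    oracle <- brute_force_qp(A, b)
    if (is.null(oracle)) {
      expect_error(solve_weights(cs), class = "caew_infeasible")
    } else {
      w <- solve_weights(cs)
      expect_equal(w$objective, oracle$objective, tolerance = 1e-6)
      expect_lt(max(abs(A %*% w$w - b)), 1e-6)
    }
  }
})

test_that("infeasible systems raise a structured error naming bad rows", {
  # two units cannot put weighted mass on an unobserved side
  t <- c(1, 1, 0, 0)
  x <- design_matrix(cbind(z = c(1, 0.9, 0.8, 0.7)))
  cs0 <- build_conditions(t, x, "binary", projection_override = 0.5)
  cs <- append_target_population(cs0, c(z = -5))
  err <- tryCatch(solve_weights(cs), error = identity)
  expect_s3_class(err, "caew_infeasible")
  expect_match(conditionMessage(err), "positivity")
  expect_true(!is.null(err$most_violated))
  expect_true("target:z" %in% err$most_violated$label)
})

test_that("weights survive a CSV round trip", {
  w <- solve_weights(build_conditions(c(1, 1, 0, 0),
                                      design_matrix(cbind(z = c(1, 0, 0, -1))),
                                      "binary", projection_override = 0.5))
  f <- tempfile(fileext = ".csv")
  write_weights(w, f)
  expect_equal(unname(read_weights(f)), w$w)
  unlink(f)
})
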