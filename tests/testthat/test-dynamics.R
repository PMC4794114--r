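test_that("eigen summaries count strictly positive real parts", {
  es <- eigen_summary(diag(c(-1, -2)))
  expect_equal(es$n_positive, 0)
  expect_false(es$has_unstable_focus)
  expect_equal(stability_class(es), "stable")

  es2 <- eigen_summary(rbind(c(1, -2), c(2, 1)))  # eigenvalues 1 +/- 2i
  expect_equal(es2$n_positive, 2)
  expect_true(es2$has_unstable_focus)
  expect_equal(stability_class(es2), "oscillatory_unstable")

  es3 <- eigen_summary(diag(c(1, -1)))
  expect_equal(stability_class(es3), "exponentially_unstable")
})

test_that("systems without auxiliaries keep the plain S-system Jacobian", {
  sys <- parse_model_file("X1' = a - b*X1^2")
  fp <- fixed_point(sys, 1, c(a = 4, b = 1))
  J <- reduced_jacobian(sys, 1, fp)
  # d/dX (a - b X^2) = -2 b X = -4 at X* = 2
  expect_equal(unname(J[1, 1]), -4)
})

test_that("auxiliary elimination matches the analytic reduced derivative", {
  # dX/dt = a*d^-1 - b*X with 0 = 1 + X - d; dominance selects d = X,
  # so the reduced law is a/X - bX with derivative -a/X^2 - b
  sys <- parse_model_file(c("X1' = a*d1^-1 - b*X1", "0 = 1 + X1 - d1"))
  params <- c(a = 100, b = 1)
  case <- c(1, 1, 2, 1)  # d1 = X1 branch
  fp <- fixed_point(sys, case, params)
  x <- unname(fp$concentrations["X1"])
  expect_equal(x, 10)    # X = sqrt(a/b)
  J <- reduced_jacobian(sys, case, fp)
  expect_equal(unname(J[1, 1]), -params[["a"]] / x^2 - params[["b"]])
})

test_that("reduced Jacobians match finite differences of the reduced field", {
  set.seed(51)
  n_checked <- 0
  for (s in 1:10) {
    sys <- random_gma_fixture(fixture_spec(n_dynamic = 3, n_auxiliary = 1,
                                           term_range = c(1, 2),
                                           seed = 600 + s, structure = "feedback"))
    rep <- enumerate_repertoire(sys)
    for (n in utils::head(rep$valid_cases, 2)) {
      w <- interior_parameter_point(sys, n)
      fp <- fixed_point(sys, n, w$params)
      if (max(abs(fp$log10)) > 4) next
      J <- tryCatch(reduced_jacobian(sys, n, fp), error = function(e) NULL)
      if (is.null(J)) next
      ss <- extract_ssystem(sys, n)
      dyn <- sys$dynamic
      f <- function(x) {
        names(x) <- dyn
        v <- designspacer:::solve_auxiliaries(ss, c(x, w$params))
        designspacer:::eval_rhs(ss, v)[seq_along(dyn)]
      }
      x0 <- fp$concentrations[dyn]
      Jfd <- vapply(seq_along(dyn), function(j) {
        h <- x0[j] * 1e-6
        xp <- x0; xm <- x0; xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
        (f(xp) - f(xm)) / (2 * h)
      }, numeric(length(dyn)))
      ev <- sort(Re(eigen(J, only.values = TRUE)$values))
      evfd <- sort(Re(eigen(Jfd, only.values = TRUE)$values))
      expect_equal(ev, evfd, tolerance = 1e-6)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 8)
})

test_that("a one-variable turnover system is stable with no oscillatory potential", {
  sys <- parse_model_file("X1' = a - b*X1")
  cd <- classify_case_dynamics(sys, 1, seed = 1)
  expect_equal(cd$class, "stable")
  expect_false(cd$oscillatory_potential)
})

test_that("dynamics classification is deterministic under a fixed seed", {
  circ <- relax_circ()
  a <- classify_case_dynamics(circ$system, 23, seed = 5)
  b <- classify_case_dynamics(circ$system, 23, seed = 5)
  expect_identical(a$focus_point, b$focus_point)
  expect_identical(a$oscillatory_potential, b$oscillatory_potential)
  expect_identical(a$eigenvalues, b$eigenvalues)
})

test_that("hit-and-run probes stay inside the case polytope", {
  circ <- relax_circ()
  maps <- designspacer:::case_maps(circ$system, 23)
  w <- interior_parameter_point(circ$system, 23)
  lb <- circ$system$bounds["lb", maps$znames]
  ub <- circ$system$bounds["ub", maps$znames]
  pr <- designspacer:::hit_and_run(maps$W, maps$w0, lb, ub, w$log10,
                                   n = 50, seed = 9)
  expect_equal(nrow(pr), 50)
  for (i in seq_len(nrow(pr))) {
    expect_true(all(pr[i, ] >= lb - 1e-9 & pr[i, ] <= ub + 1e-9))
    expect_gte(min(maps$W %*% pr[i, ] + maps$w0), -1e-9)
  }
  # deterministic
  pr2 <- designspacer:::hit_and_run(maps$W, maps$w0, lb, ub, w$log10,
                                    n = 50, seed = 9)
  expect_identical(pr, pr2)
})
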