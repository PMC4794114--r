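test_that("single-term equations produce no dominance rows", {
  sys <- parse_model_file("X1' = a - b*X1")
  conds <- dominance_conditions(sys, 1)
  expect_equal(conds$status, "ok")
  expect_equal(nrow(conds$W), 0)
  vr <- assess_validity(conds)
  expect_true(vr$valid)
})

test_that("a two-term numerator produces one parameter-only inequality", {
  sys <- parse_model_file("X1' = a + c - b*X1")
  conds <- dominance_conditions(sys, c(1, 1))  # a dominant
  expect_equal(nrow(conds$W), 1)
  # row is log a - log c >= 0
  expect_equal(conds$W[1, ], c(a = 1, b = 0, c = -1), ignore_attr = TRUE)
  expect_equal(unname(conds$w0), 0)
})

test_that("row counts equal the number of competing terms", {
  circ <- relax_circ()
  sig <- compute_system_signature(circ$system)
  for (n in c(1, 23, 36)) {
    conds <- dominance_conditions(circ$system, n)
    expect_equal(nrow(conds$W), sum(sig$pairs - 1L))  # 6 for this family
  }
})

test_that("row values equal directly evaluated log term ratios", {
  set.seed(21)
  n_rows_checked <- 0
  for (s in 1:12) {
    sys <- random_gma_fixture(fixture_spec(n_dynamic = 3, n_auxiliary = 1,
                                           seed = 200 + s, structure = "feedback"))
    total <- total_case_count(sys)
    n <- sample(total, 1)
    conds <- dominance_conditions(sys, n)
    if (conds$status != "ok" || !nrow(conds$W)) next
    for (j in 1:4) {
      z <- stats::runif(ncol(conds$W), -2, 2)
      vals <- drop(conds$W %*% z + conds$w0)
      for (r in seq_along(vals)) {
        direct <- direct_row_value(sys, n, z, conds$provenance[r, ])
        expect_equal(vals[r], direct, tolerance = 1e-9)
        n_rows_checked <- n_rows_checked + 1
      }
    }
  }
  expect_gte(n_rows_checked, 40)
})

test_that("per-parameter tolerances bound the validity interval exactly", {
  sys <- parse_model_file("X1' = a + c - b*X1")
  pt <- c(a = 10, c = 1, b = 1)
  tol <- parameter_tolerances(sys, c(1, 1), pt)
  expect_equal(tol["lb", "a"], 0)   # a may fall to c (log10 c = 0)
  expect_equal(tol["ub", "a"], 6)   # and rise to its bound
  expect_equal(tol["ub", "c"], 1)   # c may rise to a
  expect_equal(unname(tol[, "b"]), c(-6, 6))  # b unconstrained

  # stepping inside keeps validity, outside breaks it (random fixtures)
  set.seed(31)
  for (s in 1:6) {
    sys <- random_gma_fixture(fixture_spec(n_dynamic = 2, seed = 300 + s))
    rep <- enumerate_repertoire(sys)
    for (n in utils::head(rep$valid_cases, 2)) {
      w <- interior_parameter_point(sys, n)
      tl <- parameter_tolerances(sys, n, w$params)
      conds <- dominance_conditions(sys, n)
      for (pname in colnames(tl)) {
        z <- log10(w$params[colnames(conds$W)])
        inside <- outside <- z
        inside[pname] <- min(tl["ub", pname] - 1e-6, max(tl["lb", pname] + 1e-6,
                                                         z[pname]))
        ok_in <- !nrow(conds$W) || min(conds$W %*% inside + conds$w0) >= -1e-9
        expect_true(ok_in)
        if (tl["ub", pname] < sys$bounds["ub", pname] - 1e-6) {
          outside[pname] <- tl["ub", pname] + 1e-4
          expect_lt(min(conds$W %*% outside + conds$w0), 0)
        }
      }
    }
  }
})

test_that("points violating the conditions are rejected for tolerances", {
  sys <- parse_model_file("X1' = a + c - b*X1")
  expect_error(parameter_tolerances(sys, c(1, 1), c(a = 1, c = 10, b = 1)),
               "does not satisfy")
})
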