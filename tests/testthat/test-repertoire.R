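test_that("a one-term system has a single valid phenotype", {
  sys <- parse_model_file("X1' = a - b*X1")
  rep <- enumerate_repertoire(sys)
  expect_equal(nrow(rep$table), 1)
  expect_equal(rep$valid_cases, 1)
})

test_that("both phenotypes of a two-source production are valid", {
  sys <- parse_model_file("X1' = a + c - b*X1")
  rep <- enumerate_repertoire(sys)
  expect_equal(rep$valid_cases, c(1, 2))
  expect_true(all(rep$table$slack > 0))
})

test_that("witnesses satisfy their own dominance rows with the reported slack", {
  set.seed(41)
  for (s in 1:10) {
    sys <- random_gma_fixture(fixture_spec(n_dynamic = sample(2:3, 1),
                                           n_auxiliary = sample(0:1, 1),
                                           term_range = c(1, 2),
                                           seed = 400 + s))
    rep <- enumerate_repertoire(sys)
    for (n in rep$valid_cases) {
      vr <- rep$results[[n]]
      conds <- dominance_conditions(sys, n)
      marg <- if (nrow(conds$W))
        min(drop(conds$W %*% vr$witness_log10 + conds$w0)) else Inf
      expect_gte(marg + 1e-9, vr$slack)
      expect_true(all(vr$witness_log10 >= sys$bounds["lb", ] + vr$slack - 1e-9))
      expect_true(all(vr$witness_log10 <= sys$bounds["ub", ] - vr$slack + 1e-9))
    }
  }
})

test_that("shrinking the bounds never turns an invalid case valid", {
  set.seed(43)
  for (s in 1:8) {
    sys <- random_gma_fixture(fixture_spec(n_dynamic = 2, n_auxiliary = 1,
                                           term_range = c(1, 2),
                                           seed = 500 + s))
    wide <- enumerate_repertoire(sys)
    narrow_bounds <- sys$bounds
    narrow_bounds["lb", ] <- -3; narrow_bounds["ub", ] <- 3
    narrow <- enumerate_repertoire(sys, bounds = narrow_bounds)
    expect_true(all(narrow$valid_cases %in% wide$valid_cases))
  }
})

test_that("the relaxation-oscillator count is insensitive to the bound width", {
  circ <- relax_circ()
  for (w in c(3, 6, 9)) {
    b <- circ$system$bounds
    b["lb", ] <- pmax(b["lb", ], -w); b["ub", ] <- pmin(b["ub", ], w)
    rep <- enumerate_repertoire(circ$system, bounds = b)
    expect_equal(length(rep$valid_cases), 15)
  }
})

test_that("interior points distinguish invalid cases from excluding constraints", {
  circ <- relax_circ()
  expect_error(interior_parameter_point(circ$system, 2), "not valid")
  # a constraint that empties case 23's region: force the activator fold to 1
  hard <- linear_constraints(eq_A = matrix(1, 1, 1, dimnames = list(NULL, "rA1")),
                             eq_b = 0)
  expect_error(interior_parameter_point(circ$system, 23, constraints = hard),
               "constraints exclude")
  # compatible constraint: time normalization keeps the case realizable
  w <- interior_parameter_point(circ$system, 23, constraints = timescale_norm())
  expect_equal(mean(log10(w$params[c("g1", "g2", "g3", "g4")])), 0,
               tolerance = 1e-9)
  expect_gt(w$slack, 0)
})

test_that("repertoire tables serialize to CSV and JSON", {
  rep <- enumerate_repertoire(parse_model_file("X1' = a + c - b*X1"))
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  write_repertoire_csv(rep, csv)
  df <- utils::read.csv(csv)
  expect_equal(df$case_number, 1:2)
  expect_equal(df$status, rep$table$status)
  write_repertoire_json(rep, json, seed = 7)
  payload <- jsonlite::read_json(json)
  expect_equal(payload$phenotypic_fraction$valid, 2)
  expect_equal(payload$seed, 7)
  unlink(c(csv, json))
})
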