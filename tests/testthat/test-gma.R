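test_that("system signatures read off term counts in equation order", {
  circ <- relax_circ()
  expect_equal(compute_system_signature(circ$system)$flat, "311121113121")
  expect_equal(total_case_count(circ$system), 36)

  one <- parse_model_file("X1' = a - b*X1")
  expect_equal(compute_system_signature(one)$flat, "11")
  expect_equal(total_case_count(one), 1)

  two <- gma_system(list(
    gma_equation("X1", list(power_law_term(params = c(a = 1)),
                            power_law_term(params = c(b = 1), vars = c(X2 = 1))),
                 list(power_law_term(params = c(c = 1), vars = c(X1 = 1)))),
    gma_equation("X2", list(power_law_term(params = c(d = 1))),
                 list(power_law_term(params = c(e = 1), vars = c(X2 = 1)),
                      power_law_term(params = c(f = 1), vars = c(X2 = 2)),
                      power_law_term(params = c(h = 1), vars = c(X1 = 1, X2 = 1))))))
  expect_equal(compute_system_signature(two)$flat, "2113")
  expect_equal(total_case_count(two), 6)
})

test_that("case numbering follows digital counting, negative index fastest", {
  sig <- compute_system_signature(relax_circ()$system)
  expect_equal(number_to_signature(1, sig)$flat, "111111111111")
  expect_equal(number_to_signature(2, sig)$flat, "111111111121")
  expect_equal(number_to_signature(5, sig)$flat, "111111113111")
  expect_equal(number_to_signature(36, sig)$flat, "311121113121")
  expect_equal(signature_to_number(c(2,1,1,1,2,1,1,1,3,1,1,1), sig), 23)
  expect_error(number_to_signature(37, sig), "out of range")
  expect_error(signature_to_number(c(4,1,1,1,2,1,1,1,3,1,1,1), sig), "range")
})

test_that("signature/number conversion is a bijection on random signatures", {
  set.seed(7)
  for (rep in 1:25) {
    neq <- sample(1:5, 1)
    pairs <- matrix(sample(1:4, 2 * neq, replace = TRUE), ncol = 2)
    sig <- structure(list(pairs = pairs,
                          flat = paste(t(pairs), collapse = "")),
                     class = "system_signature")
    total <- total_case_count(sig)
    back <- vapply(seq_len(total), function(n)
      signature_to_number(number_to_signature(n, sig), sig), 1L)
    expect_identical(back, seq_len(total))
    # enumeration produces exactly `total` distinct signatures
    flats <- vapply(seq_len(total), function(n)
      number_to_signature(n, sig)$flat, "")
    expect_equal(length(unique(flats)), total)
  }
})

test_that("extract_ssystem keeps exactly the selected dominant terms", {
  circ <- relax_circ()
  ss <- extract_ssystem(circ$system, 23)
  expect_true(all(compute_system_signature(ss)$pairs == 1L))
  expect_identical(ss$dynamic, circ$system$dynamic)
  expect_identical(ss$auxiliary, circ$system$auxiliary)
  expect_identical(ss$parameters, circ$system$parameters)

  toy <- parse_model_file("X1' = a + c*X1 - b*X1")
  ss2 <- extract_ssystem(toy, c(2, 1))
  tm <- ss2$equations[[1]]$positive[[1]]
  expect_equal(names(tm$params), "c")
  expect_equal(unname(tm$vars["X1"]), 1)
})

test_that("malformed systems are rejected", {
  expect_error(power_law_term(const = -1), "positive")
  expect_error(power_law_term(params = c(1)), "named")
  expect_error(gma_equation("X", list(), list(power_law_term(1))), "non-empty")
  # algebraic convention: auxiliary must be the bare single negative term
  expect_error(gma_equation("d", list(power_law_term(1)),
                            list(power_law_term(2, vars = c(d = 1))),
                            kind = "algebraic"), "algebraic")
  # duplicate targets
  eq <- gma_equation("X1", list(power_law_term(params = c(a = 1))),
                     list(power_law_term(params = c(b = 1), vars = c(X1 = 1))))
  expect_error(gma_system(list(eq, eq)), "distinct")
  # undeclared variable
  bad <- gma_equation("X1", list(power_law_term(params = c(a = 1), vars = c(Y = 1))),
                      list(power_law_term(params = c(b = 1), vars = c(X1 = 1))))
  expect_error(gma_system(list(bad)), "not defined")
})

test_that("set_bounds updates and validates the parameter box", {
  sys <- parse_model_file("X1' = a - b*X1")
  sys <- set_bounds(sys, a = c(-2, 2))
  expect_equal(unname(sys$bounds[, "a"]), c(-2, 2))
  expect_error(set_bounds(sys, q = c(0, 1)), "unknown")
  expect_error(set_bounds(sys, a = c(2, -2)), "bound")
})
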