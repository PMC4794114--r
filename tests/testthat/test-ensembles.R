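test_that("a one-case ensemble reduces to the interior parameter point", {
  sys <- parse_model_file("X1' = a + c - b*X1")
  rep <- enumerate_repertoire(sys)
  ens <- co_localize(sys, rep, 1, axes = c("a", "b"))
  expect_true(ens$feasible)
  w <- interior_parameter_point(sys, 1)
  expect_equal(ens$slack, w$slack, tolerance = 1e-9)
})

test_that("co-localized ensembles re-verify by point membership", {
  circ <- relax_circ()
  rep <- relax_rep()
  ens <- co_localize(circ$system, rep, c(1, 23, 36), axes = c("g2", "g4"))
  expect_true(ens$feasible)
  cache <- designspacer:::case_cache(circ$system, rep)
  for (i in seq_along(ens$cases)) {
    pt <- c(ens$shared, 10^ens$axis_log10[i, ])
    df <- cases_at_point(circ$system, rep, pt, cache = cache)
    expect_true(ens$cases[i] %in% df$case_number)
    expect_gte(df$margin[df$case_number == ens$cases[i]], ens$slack - 1e-9)
  }
})

test_that("subsets of a co-localizable ensemble stay co-localizable", {
  circ <- relax_circ()
  rep <- relax_rep()
  full <- co_localize(circ$system, rep, c(1, 13, 23, 36), axes = c("g2", "g4"))
  expect_true(full$feasible)
  for (drop in 1:4) {
    sub <- co_localize(circ$system, rep, c(1, 13, 23, 36)[-drop],
                       axes = c("g2", "g4"))
    expect_true(sub$feasible)
    expect_gte(sub$slack + 1e-9, full$slack)
  }
})

test_that("the exact maximal subset search matches brute force on a fixture", {
  sys <- random_gma_fixture(fixture_spec(n_dynamic = 2, n_auxiliary = 1,
                                         term_range = c(1, 3), seed = 19))
  rep <- enumerate_repertoire(sys)
  axes <- sys$parameters[1:2]
  ms <- maximal_coexistent_subset(sys, rep, axes = axes)
  # brute force over every subset
  best <- 0; best_sets <- list()
  valid <- rep$valid_cases
  for (k in seq_along(valid)) {
    for (sub in utils::combn(valid, k, simplify = FALSE)) {
      ens <- co_localize(sys, rep, sub, axes = axes)
      if (ens$feasible && k > best) { best <- k; best_sets <- list(sub) }
      else if (ens$feasible && k == best) best_sets <- c(best_sets, list(sub))
    }
  }
  expect_equal(length(ms$subset), best)
  expect_true(any(vapply(best_sets, function(s) all(s == ms$subset), TRUE)))
})

test_that("ordered ensembles respect the requested axis order", {
  sys <- parse_model_file("X1' = a + c - b*X1")
  rep <- enumerate_repertoire(sys)
  # case 1: a dominant (low c); case 2: c dominant (high c)
  oe <- ordered_ensemble(sys, rep, c(1, 2), axis = "c")
  expect_true(oe$feasible)
  expect_lte(oe$axis_log10[1, "c"], oe$axis_log10[2, "c"] - 0.5)
  # the reverse order is impossible along the same axis
  oe2 <- ordered_ensemble(sys, rep, c(2, 1), axis = "c")
  expect_false(oe2$feasible)
  # single case trivially feasible
  expect_true(ordered_ensemble(sys, rep, 1, axis = "c")$feasible)
})

test_that("the oscillatory phenotypes of the dual-dual design can be phased
          along the repressor-inactivation axis", {
  circ <- d12_circ()
  rep <- d12_rep()
  cache <- designspacer:::case_cache(circ$system, rep)
  # pairwise phasings consistent with the slice adjacency are realizable
  for (pair in list(c(18, 16), c(16, 43), c(43, 45))) {
    oe <- ordered_ensemble(circ$system, rep, pair, axis = "g4", margin = 0.25)
    expect_true(oe$feasible, info = paste(pair, collapse = "<"))
    expect_gte(diff(oe$axis_log10[, "g4"]), 0.25 - 1e-9)
    for (k in 1:2) {
      pt <- c(oe$shared, stats::setNames(10^oe$axis_log10[k, "g4"], "g4"))
      df <- cases_at_point(circ$system, rep, pt, cache = cache)
      expect_true(oe$cases[k] %in% df$case_number)
    }
  }
  # the opposite phasing of the outermost pair is not realizable
  oe_rev <- ordered_ensemble(circ$system, rep, c(45, 18), axis = "g4",
                             margin = 0.25)
  expect_false(oe_rev$feasible)
})
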