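test_that("recast GMA and rational trajectories agree", {
  circ <- relax_circ()
  pt <- interior_parameter_point(circ$system, 23,
                                 constraints = timescale_norm())$params
  tr_rat <- simulate_full_system(circ$rational, pt, t_end = 20, case = 23,
                                 gma = circ$system, n_out = 400)
  tr_gma <- simulate_full_system(circ$system, pt, t_end = 20, case = 23,
                                 n_out = 400)
  rel <- abs(tr_rat$states - tr_gma$states) / pmax(abs(tr_rat$states), 1e-300)
  expect_lt(max(rel), 1e-6)
  expect_true(all(tr_gma$states > 0))
})

test_that("the constitutive cascade relaxes monotonically to its steady state", {
  circ <- build_circuit("D.5")
  rep <- enumerate_repertoire(circ$system)
  n <- rep$valid_cases[1]
  pt <- interior_parameter_point(circ$system, n,
                                 constraints = timescale_norm())$params
  fp <- fixed_point(circ$system, n, pt)
  start <- fp$concentrations[circ$system$dynamic] * 5
  tr <- simulate_full_system(circ$rational, pt, t_end = 50, gma = circ$system,
                             initial_state = start, n_out = 500)
  expect_equal(classify_trajectory(tr, "X4"), "monotone_or_none")
  # approaches a steady state: final derivative is tiny relative to state
  final <- tr$states[nrow(tr$states), ]
  expect_lt(max(abs(final - tr$states[nrow(tr$states) - 1, ]) / final), 1e-4)
})

test_that("trajectory classification separates the canonical waveforms", {
  tt <- seq(0, 100, length.out = 2000)
  mk <- function(y) structure(list(time = tt, states = cbind(X4 = y)),
                              class = "trajectory")
  expect_equal(classify_trajectory(mk(2 + sin(tt))), "sustained_oscillation")
  expect_equal(classify_trajectory(mk(2 + exp(-0.05 * tt) * sin(tt))),
               "damped_oscillation")
  expect_equal(classify_trajectory(mk(2 + exp(-0.05 * tt))), "monotone_or_none")
  expect_equal(classify_trajectory(mk(rep(2, length(tt)))), "monotone_or_none")
  # growing transients are not called sustained
  expect_equal(classify_trajectory(mk(2 + exp(0.03 * tt) * sin(tt) * 1e-3)),
               "monotone_or_none")
})

test_that("trajectories serialize to CSV", {
  circ <- relax_circ()
  pt <- interior_parameter_point(circ$system, 1)$params
  tr <- simulate_full_system(circ$system, pt, t_end = 5, case = 1, n_out = 50)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  df <- utils::read.csv(f)
  expect_equal(nrow(df), 50)
  expect_equal(names(df), c("time", "X1", "X2", "X3", "X4"))
  unlink(f)
})

test_that("invalid inputs to the integrator raise errors", {
  circ <- relax_circ()
  pt <- interior_parameter_point(circ$system, 1)$params
  expect_error(simulate_full_system(circ$rational, pt), "initial_state")
  expect_error(simulate_full_system(circ$rational, pt, case = 1,
                                    gma = circ$system,
                                    initial_state = c(X1 = -1, X2 = 1, X3 = 1, X4 = 1)),
               "strictly positive")
  bad <- pt; bad[1] <- -bad[1]
  expect_error(simulate_full_system(circ$rational, bad, case = 1,
                                    gma = circ$system), "positive")
})
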