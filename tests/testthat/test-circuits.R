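test_that("the catalog maps identifiers to mode indices", {
  cat_ <- design_catalog()
  expect_equal(nrow(cat_), 16)
  expect_equal(unlist(cat_[cat_$id == "D.14", 2:5]), c(pi1 = 1, delta1 = 1, pi3 = 1, delta3 = 0))
  expect_equal(unlist(cat_[cat_$id == "D.3", 2:5]), c(pi1 = 0, delta1 = 0, pi3 = 0, delta3 = 1))
  expect_equal(unlist(cat_[cat_$id == "D.9", 2:5]), c(pi1 = 0, delta1 = 0, pi3 = 1, delta3 = 0))
})

test_that("circuit signatures follow the per-gene mode rules", {
  expect_equal(compute_system_signature(build_circuit(1, 1, 1, 0)$system)$flat,
               "311121113121")
  expect_equal(total_case_count(build_circuit("D.12")$system), 81)
  expect_equal(total_case_count(build_circuit("D.5")$system), 16)
  # dual genes contribute (3,1)+(3,1), single/constitutive (2,1)+(2,1),
  # protein equations (1,1): checked against every design's denominator
  for (id in design_catalog()$id) {
    circ <- build_circuit(id)
    sig <- compute_system_signature(circ$system)
    per_gene <- c(dual = 9L, single = 4L, constitutive = 4L)
    expect_equal(total_case_count(sig),
                 unname(per_gene[circ$modes["gene1"]] * per_gene[circ$modes["gene3"]]))
    pairs <- sig$pairs
    expect_equal(pairs[2, ], c(P = 1L, N = 1L))  # protein equations
    expect_equal(pairs[4, ], c(P = 1L, N = 1L))
  }
})

test_that("valid counts factorize over gene modes as dual 5, single 3, constitutive 2", {
  screen <- design_screen_cached()
  factor_of <- c(dual = 5L, single = 3L, constitutive = 2L)
  for (id in design_catalog()$id) {
    circ <- screen$details[[id]]$circuit
    expect_equal(screen$table$valid[screen$table$design == id],
                 unname(factor_of[circ$modes["gene1"]] * factor_of[circ$modes["gene3"]]),
                 info = id)
  }
})

test_that("the relaxation oscillator alias matches its indices", {
  circ <- relax_circ()
  expect_equal(circ$id, "D.14")
  expect_equal(unname(circ$indices), c(1, 1, 1, 0))
  expect_equal(circ$modes[["gene1"]], "dual")
  expect_equal(circ$modes[["gene3"]], "single")
})

test_that("fold-change bounds encode the transcriptional modes", {
  circ <- relax_circ()
  expect_equal(unname(circ$system$bounds[, "rA1"]), c(0, 6))
  expect_equal(unname(circ$system$bounds[, "rA3"]), c(0, 6))
  expect_false("rR1" %in% circ$system$parameters)  # competitive, fold pinned to 1
  d3 <- build_circuit("D.3")
  expect_equal(unname(d3$system$bounds[, "rR1"]), c(-6, 0))
  expect_equal(unname(d3$system$bounds[, "rR3"]), c(-6, 0))
})

test_that("dominant-term reductions recover the simpler architectures", {
  # the dual-dual design's oscillatory phenotypes reduce to the simpler
  # designs: compare reduced net kinetic orders
  d12 <- d12_circ()
  K16 <- designspacer:::case_maps(d12$system, 16)$K_reduced
  K43 <- designspacer:::case_maps(d12$system, 43)$K_reduced
  K18 <- designspacer:::case_maps(d12$system, 18)$K_reduced

  d9 <- build_circuit("D.9")
  scr <- design_screen_cached()
  osc9 <- as.integer(strsplit(scr$table$oscillatory_cases[9], ";")[[1]])
  K9 <- designspacer:::case_maps(d9$system, osc9)$K_reduced
  expect_equal(unname(K16), unname(K9))

  d10 <- build_circuit("D.10")
  osc10 <- as.integer(strsplit(scr$table$oscillatory_cases[10], ";")[[1]])
  K10s <- lapply(osc10, function(n) designspacer:::case_maps(d10$system, n)$K_reduced)
  expect_true(any(vapply(K10s, function(K) isTRUE(all.equal(unname(K), unname(K43))), TRUE)))

  d3 <- build_circuit("D.3")
  osc3 <- as.integer(strsplit(scr$table$oscillatory_cases[3], ";")[[1]])
  K3 <- designspacer:::case_maps(d3$system, osc3)$K_reduced
  expect_equal(unname(K18), unname(K3))
})

test_that("circuit models round-trip through the text format", {
  for (id in c("D.14", "D.12", "D.1")) {
    sys <- build_circuit(id)$system
    txt <- write_model_file(sys)
    sys2 <- parse_model_file(txt)
    expect_identical(write_model_file(sys2), txt)
    expect_equal(compute_system_signature(sys2)$flat,
                 compute_system_signature(sys)$flat)
  }
})

test_that("screens serialize to a catalog-shaped CSV", {
  screen <- design_screen_cached()
  f <- tempfile(fileext = ".csv")
  write_screen_csv(screen, f)
  df <- utils::read.csv(f)
  expect_equal(nrow(df), 16)
  expect_equal(df$design, design_catalog()$id)
  expect_true(all(c("valid", "total", "n_oscillatory") %in% names(df)))
  unlink(f)
})
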