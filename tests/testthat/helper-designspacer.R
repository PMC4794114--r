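# Shared fixtures, independent oracles, and a lazy cache so expensive
# results (repertoires, the design screen, slices) are computed once per
# test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

relax_circ <- function() cached("relax_circ", relaxation_oscillator())

relax_rep <- function() cached("relax_rep",
                               enumerate_repertoire(relax_circ()$system))

# equality constraint pinning the geometric-mean inactivation rate to 1/h
# (the growth-rate time normalization used for simulations and figures)
timescale_norm <- function() linear_constraints(
  eq_A = matrix(0.25, 1, 4, dimnames = list(NULL, c("g1", "g2", "g3", "g4"))),
  eq_b = 0)

relax_cd23 <- function() cached("relax_cd23",
  classify_case_dynamics(relax_circ()$system, 23,
                         constraints = timescale_norm(), seed = 24))

design_screen_cached <- function() cached("screen", screen_designs(seed = 1))

d12_circ <- function() cached("d12_circ", build_circuit("D.12"))
d12_rep <- function() cached("d12_rep", enumerate_repertoire(d12_circ()$system))

# one-gene positive-feedback (self-activating) circuit: bistable toy.
# X1' = a*(1 + r*(X1/K)^2) / (1 + (X1/K)^2) - g*X1, recast with one
# binding polynomial d1.
bistable_toy <- function() cached("bistable_toy", {
  num <- list(power_law_term(params = c(a = 1)),
              power_law_term(params = c(a = 1, r = 1, K = -2), vars = c(X1 = 2)))
  den <- list(power_law_term(1),
              power_law_term(params = c(K = -2), vars = c(X1 = 2)))
  model <- rational_model(list(
    X1 = list(ratio_block(+1, num, den),
              ratio_block(-1, power_law_term(params = c(g = 1), vars = c(X1 = 1))))))
  sys <- recast_to_gma(model, aux_names = "d1")
  sys <- set_bounds(sys, r = c(0, 6))
  list(model = model, system = sys)
})

# positive real steady states of the bistable toy's full rational model:
# g*x*(1 + (x/K)^2) = a*(1 + r*(x/K)^2), a cubic solved exactly (polyroot)
bistable_roots <- function(params) {
  a <- params[["a"]]; r <- params[["r"]]; K <- params[["K"]]; g <- params[["g"]]
  # g/K^2 x^3 - a r/K^2 x^2 + g x - a = 0
  z <- polyroot(c(-a, g, -a * r / K^2, g / K^2))
  x <- Re(z[abs(Im(z)) < 1e-8 * Mod(z) | abs(Im(z)) < 1e-12])
  sort(x[x > 0])
}

# independent root oracle: Newton iteration on the S-system balance in
# original concentrations, finite-difference Jacobian, started from a
# perturbed point
newton_fixed_point <- function(ssystem, params, start, max_iter = 200) {
  vars <- names(start)
  G <- function(x) {
    names(x) <- vars
    v <- c(x, params)
    vapply(ssystem$equations, function(eq) {
      # residual in log space for scale invariance
      p <- sum(vapply(eq$positive, function(tm) designspacer:::eval_term(tm, v), 0))
      n <- sum(vapply(eq$negative, function(tm) designspacer:::eval_term(tm, v), 0))
      log(p) - log(n)
    }, 0)
  }
  u <- log(start)
  for (it in seq_len(max_iter)) {
    x <- exp(u)
    g0 <- G(x)
    if (max(abs(g0)) < 1e-12) break
    J <- vapply(seq_along(u), function(j) {
      h <- 1e-7
      up <- u; up[j] <- up[j] + h
      (G(exp(up)) - g0) / h
    }, numeric(length(u)))
    J <- matrix(J, length(u), length(u))
    step <- tryCatch(solve(J, g0), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    step <- pmin(pmax(step, -5), 5)
    u <- u - step
  }
  x <- exp(u)
  names(x) <- vars
  if (max(abs(G(x))) > 1e-10) return(NULL)
  x
}

# brute-force maximin LP oracle by vertex enumeration: maximize delta s.t.
# W z + w0 >= delta, lb + delta <= z <= ub - delta, for small dimensions
vertex_maximin <- function(W, w0, lb, ub) {
  p <- length(lb)
  # slack rows plus the hard parameter bounds (delta-coefficient 0), which
  # can be active at the optimum when delta < 0
  A <- rbind(if (nrow(W)) cbind(-W, 1), cbind(-diag(p), 1), cbind(diag(p), 1),
             cbind(-diag(p), 0), cbind(diag(p), 0))
  b <- c(if (nrow(W)) w0, -lb, ub, -lb, ub)
  n <- p + 1L
  best <- -Inf; bestx <- NULL
  for (idx in utils::combn(nrow(A), n, simplify = FALSE)) {
    M <- A[idx, , drop = FALSE]
    if (abs(det(M)) < 1e-12) next
    x <- tryCatch(solve(M, b[idx]), error = function(e) NULL)
    if (is.null(x)) next
    if (all(A %*% x <= b + 1e-9) && all(x[seq_len(p)] >= lb - 1e-9) &&
        all(x[seq_len(p)] <= ub + 1e-9)) {
      if (x[n] > best) { best <- x[n]; bestx <- x }
    }
  }
  list(delta = best, x = bestx)
}

# direct evaluation of a dominance row: log10(dominant/competing) at the
# case's steady state computed straight from the selected terms
direct_row_value <- function(system, case, z, row_info) {
  fp <- fixed_point(system, case, 10^stats::setNames(z, colnames(system$bounds)))
  vals <- c(fp$concentrations, 10^stats::setNames(z, colnames(system$bounds)))
  eq <- system$equations[[row_info$equation]]
  sel <- designspacer:::case_pairs(system, case)
  side <- if (row_info$side == "pos") "positive" else "negative"
  k_sel <- sel[row_info$equation, if (row_info$side == "pos") 1 else 2]
  t_sel <- eq[[side]][[k_sel]]
  t_cmp <- eq[[side]][[row_info$competitor]]
  designspacer:::eval_term_log10(t_sel, vals) -
    designspacer:::eval_term_log10(t_cmp, vals)
}

rand_lhs <- function(n, lb, ub) {
  sapply(seq_along(lb), function(j) stats::runif(n, lb[j], ub[j]))
}
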