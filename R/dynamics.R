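#' Reduced Jacobian of an S-system case at a fixed point
#'
#' Builds the full Jacobian of the case's S-system over all dependent
#' variables, entries `(g_ij T+_i - h_ij T-_i)/X_j` evaluated at the fixed
#' point, then eliminates the auxiliary variables by the implicit function
#' theorem: `J = A - B C^-1 D`, where `(A, B; D, C)` are the blocks over
#' (dynamic; auxiliary) variables.  The eigenvalues of `J` classify the
#' phenotype's local dynamics.
#'
#' @param system a [gma_system()].
#' @param case case number, digit vector or `ssystem_case`.
#' @param fp a [fixed_point()] for this case (or a named vector of dependent
#'   variable concentrations).
#' @param params named parameter vector; taken from `fp` when omitted.
#' @return Square matrix over the dynamic variables.
#' @export
reduced_jacobian <- function(system, case, fp, params = NULL) {
  if (inherits(fp, "fixed_point")) {
    if (is.null(params)) params <- fp$params
    x <- fp$concentrations
  } else x <- fp
  if (is.null(params)) stop("parameter values are required")
  sel <- case_pairs(system, case)
  dep <- dependent_vars(system)
  values <- c(x[dep], params)
  n <- length(dep)
  J <- matrix(0, n, n, dimnames = list(dep, dep))
  for (i in seq_len(n)) {
    eq <- system$equations[[i]]
    tp <- eq$positive[[sel[i, 1]]]; tn <- eq$negative[[sel[i, 2]]]
    Tp <- eval_term(tp, values); Tn <- eval_term(tn, values)
    for (j in seq_len(n)) {
      g <- tp$vars[dep[j]] %||0% 0
      h <- tn$vars[dep[j]] %||0% 0
      if (g != 0 || h != 0) J[i, j] <- (g * Tp - h * Tn) / values[[dep[j]]]
    }
  }
  kinds <- vapply(system$equations, `[[`, "", "kind")
  dyn <- which(kinds == "differential"); aux <- which(kinds == "algebraic")
  if (!length(aux)) return(J[dyn, dyn, drop = FALSE])
  A <- J[dyn, dyn, drop = FALSE]; B <- J[dyn, aux, drop = FALSE]
  C <- J[aux, aux, drop = FALSE]; D <- J[aux, dyn, drop = FALSE]
  sv <- svd(C, nu = 0, nv = 0)$d
  if (sv[length(sv)] < 1e-12 * max(sv))
    stop("auxiliary block of the Jacobian is singular")
  A - B %*% solve(C, D)
}

#' Eigenvalue summary of a Jacobian
#'
#' @param J square real matrix.
#' @param tol strict-positivity tolerance on real parts.
#' @return An object of class `eigen_summary`: `eigenvalues` (complex),
#'   `n_positive` (count with real part `> tol`), `has_unstable_focus`
#'   (a complex-conjugate pair with positive real parts).
#' @export
eigen_summary <- function(J, tol = 1e-9) {
  ev <- eigen(J, only.values = TRUE)$values
  pos <- Re(ev) > tol
  focus <- any(pos & abs(Im(ev)) > tol)
  structure(list(eigenvalues = ev, n_positive = sum(pos),
                 has_unstable_focus = focus),
            class = "eigen_summary")
}

#' @export
print.eigen_summary <- function(x, ...) {
  cat(sprintf("%d eigenvalue(s) with positive real part; unstable focus: %s\n",
              x$n_positive, x$has_unstable_focus))
  invisible(x)
}

#' Stability class from an eigenvalue summary
#'
#' `stable` (no eigenvalue with positive real part), `oscillatory_unstable`
#' (an unstable focus: complex pair with positive real parts), otherwise
#' `exponentially_unstable`.
#'
#' @param es an [eigen_summary()] (or a Jacobian matrix).
#' @return Character scalar.
#' @export
stability_class <- function(es) {
  if (is.matrix(es)) es <- eigen_summary(es)
  if (es$has_unstable_focus) "oscillatory_unstable"
  else if (es$n_positive == 0L) "stable"
  else "exponentially_unstable"
}

# eigen summary from turnover rates phi and reduced order matrix K.
# Scaling all phi by c > 0 scales every eigenvalue of diag(phi) K by c, so
# signs are scale-invariant; normalize by the fastest turnover to keep the
# strict-positivity tolerance meaningful at any absolute time scale.
phi_eigen <- function(phi, K, tol = 1e-9) {
  phi <- phi / max(phi)
  eigen_summary(diag(phi, nrow = length(phi)) %*% K, tol)
}

# largest real part over the complex (focus-capable) spectrum of the
# normalized diag(phi) K
phi_focus_objective <- function(phi, K, tol = 1e-9) {
  phi <- phi / max(phi)
  ev <- eigen(diag(phi, nrow = length(phi)) %*% K, only.values = TRUE)$values
  cx <- abs(Im(ev)) > tol
  if (!any(cx)) return(-Inf)
  max(Re(ev)[cx])
}

# Hit-and-run sampler in the case polytope {W z + w0 >= 0, lb <= z <= ub},
# optionally restricted to the affine subspace of equality constraints.
# Deterministic given seed; returns a matrix with one z per row.
hit_and_run <- function(W, w0, lb, ub, z0, n, seed, eq_A = NULL, burn = 5L) {
  p <- length(z0)
  null_proj <- NULL
  if (!is.null(eq_A) && nrow(eq_A)) {
    sv <- svd(t(eq_A))
    r <- sum(sv$d > 1e-12 * max(sv$d))
    U <- sv$u[, seq_len(r), drop = FALSE]
    null_proj <- diag(p) - U %*% t(U)
  }
  out <- matrix(NA_real_, n, p, dimnames = list(NULL, names(z0)))
  z <- z0
  rs <- local_rng(seed)
  total <- n * (1L + burn)
  k <- 0L
  for (it in seq_len(total)) {
    d <- rs$norm(p)
    if (!is.null(null_proj)) d <- drop(null_proj %*% d)
    nd <- sqrt(sum(d^2))
    if (nd < 1e-12) next
    d <- d / nd
    tmin <- -Inf; tmax <- Inf
    upd <- function(rate, slackv) {
      # slackv + t * rate >= 0
      if (rate > 1e-14) tmin <<- max(tmin, -slackv / rate)
      else if (rate < -1e-14) tmax <<- min(tmax, -slackv / rate)
      else if (slackv < -1e-12) { tmin <<- Inf; tmax <<- -Inf }
    }
    if (!is.null(W) && nrow(W)) {
      rates <- drop(W %*% d); slacks <- drop(W %*% z + w0)
      for (i in seq_along(rates)) upd(rates[i], slacks[i])
    }
    for (j in seq_len(p)) {
      upd(d[j], z[j] - lb[j])
      upd(-d[j], ub[j] - z[j])
    }
    if (!is.finite(tmin) || !is.finite(tmax) || tmax <= tmin) next
    z <- z + (tmin + rs$unif(1) * (tmax - tmin)) * d
    if (it %% (1L + burn) == 0L) { k <- k + 1L; out[k, ] <- z }
    if (k >= n) break
  }
  out[seq_len(k), , drop = FALSE]
}

# seed-local RNG that does not disturb the global .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  draw <- function(fn, n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- fn(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    x
  }
  list(norm = function(n) draw(stats::rnorm, n),
       unif = function(n) draw(stats::runif, n),
       int = function(n) draw(function(k) sample.int(.Machine$integer.max, k), n))
}

#' Classify the local dynamics of a valid phenotype
#'
#' Computes the stability class at the case's slack-maximizing interior
#' point, then decides *oscillatory potential*: whether anywhere in the
#' case's region the reduced Jacobian has a complex-conjugate eigenvalue
#' pair with positive real parts (an unstable focus, the fingerprint of
#' limit-cycle oscillations born in Hopf bifurcations).
#'
#' Because the reduced Jacobian of an S-system factors as
#' `diag(phi) %*% K`, with `K` the constant matrix of reduced net kinetic
#' orders and `phi_i > 0` the per-equation turnover rates (whose log10 is
#' affine in the log10 parameters), the search is performed in turnover
#' space: (i) eigenvalues are evaluated at the witness and at `probe_budget`
#' seeded hit-and-run samples of the region; (ii) a deterministic grid scan
#' over turnover log-ratios, refined by Nelder--Mead ascent of the largest
#' complex-pair real part, proposes candidate ratios that are then checked
#' for realizability inside the region by an exact LP with equality rows
#' tying the turnover ratios.  Any realizable unstable focus sets
#' `oscillatory_potential = TRUE` and is returned as a parameter point.
#'
#' @param system a [gma_system()].
#' @param case case number, digit vector or `ssystem_case`.
#' @param bounds optional log10 bounds (default: the system's).
#' @param constraints optional [linear_constraints()].
#' @param probe_budget number of hit-and-run probe points.
#' @param seed integer seed for the probes.
#' @param eps_slack strict-slack threshold for realizability.
#' @param ratio_grid log10 turnover-ratio grid for the deterministic scan.
#' @param max_checks maximum number of candidate ratios sent to the
#'   realizability LP.
#' @return An object of class `case_dynamics`: `class` (stability class at
#'   the witness), `n_positive`, `eigenvalues`, `oscillatory_potential`,
#'   and (when found) `focus_point`, the parameter set with an unstable
#'   focus.
#' @export
classify_case_dynamics <- function(system, case, bounds = NULL,
                                   constraints = NULL, probe_budget = 200L,
                                   seed = 1L, eps_slack = 1e-6,
                                   ratio_grid = seq(-3, 3, by = 0.5),
                                   max_checks = 25L) {
  if (is.null(bounds)) bounds <- system$bounds
  maps <- case_maps(system, case)
  if (!maps$solvable) stop("case steady state is unresolvable")
  conds <- dominance_conditions(system, case)
  conds$bounds <- bounds
  vr <- assess_validity(conds, bounds, eps_slack, constraints)
  if (!vr$valid) stop("case is not valid; classify only valid phenotypes")
  znames <- maps$znames
  lb <- bounds["lb", znames]; ub <- bounds["ub", znames]
  fp0 <- fixed_point(system, case, vr$witness)
  J0 <- reduced_jacobian(system, case, fp0)
  es0 <- eigen_summary(J0)
  out <- list(case_number = if (length(case) == 1L && is.numeric(case))
    as.integer(case) else NA_integer_,
    class = stability_class(es0), n_positive = es0$n_positive,
    eigenvalues = es0$eigenvalues, witness = vr$witness,
    oscillatory_potential = es0$has_unstable_focus,
    focus_point = if (es0$has_unstable_focus) vr$witness else NULL)
  K <- maps$K_reduced
  nd <- length(system$dynamic)
  if (is.null(K) || nd < 2L || out$oscillatory_potential)
    return(structure(out, class = "case_dynamics"))
  hw <- hw0 <- eqA0 <- eqb0 <- NULL
  if (!is.null(constraints)) {
    hw <- expand_rows(constraints$W, znames); hw0 <- constraints$w0
    eqA0 <- expand_rows(constraints$eq_A, znames); eqb0 <- constraints$eq_b
  }
  L0 <- maps$L0; LZ <- maps$LZ
  # (i) deterministic turnover-ratio scan + realizability LP
  ratios <- as.matrix(expand.grid(rep(list(ratio_grid), nd - 1L)))
  fvals <- apply(ratios, 1, function(r) phi_focus_objective(c(1, 10^r), K))
  ord <- order(fvals, decreasing = TRUE)
  # local refinement of the focus objective, restricted to a trust region
  # around the grid candidate (the grid is global; refinement only resolves
  # thin bands between grid points)
  polish <- function(r0) {
    radius <- 0.75
    pen <- function(r) {
      f <- phi_focus_objective(c(1, 10^r), K)
      if (!is.finite(f)) return(1e6)
      -f + 1e4 * sum(pmax(0, abs(r - r0) - radius)^2)
    }
    if (nd == 2L) {
      op <- stats::optimize(pen, interval = r0 + c(-radius, radius))
      par <- op$minimum
    } else {
      op <- stats::optim(r0, pen, method = "Nelder-Mead",
                         control = list(maxit = 400, reltol = 1e-10))
      par <- pmin(pmax(op$par, r0 - radius), r0 + radius)
    }
    list(par = par, value = phi_focus_objective(c(1, 10^par), K))
  }
  cand <- list()
  for (k in ord[seq_len(min(8L, length(ord)))]) {
    if (!is.finite(fvals[k])) break
    pol <- polish(ratios[k, ])
    if (is.finite(pol$value) && pol$value > 1e-8)
      cand[[length(cand) + 1L]] <- pol$par
  }
  for (k in ord) {
    if (length(cand) >= max_checks) break
    if (is.finite(fvals[k]) && fvals[k] > 1e-8)
      cand[[length(cand) + 1L]] <- ratios[k, ]
  }
  if (length(cand) > max_checks) cand <- cand[seq_len(max_checks)]
  for (r in cand) {
    # realizability: turnover log-ratios relative to equation 1 equal r.
    # Preferably also pin the geometric-mean turnover to 1 (unit time scale,
    # the growth-rate normalization), falling back to ratios only.
    eqA <- LZ[-1, , drop = FALSE] - matrix(LZ[1, ], nd - 1L, ncol(LZ), byrow = TRUE)
    eqb <- r - (L0[-1] - L0[1])
    res <- lp_maximin(maps$W, maps$w0, lb, ub, hard_W = hw, hard_w0 = hw0,
                      eq_A = rbind(eqA, colMeans(LZ), eqA0),
                      eq_b = c(eqb, -mean(L0) + mean(c(0, r)), eqb0))
    if (!(res$status == "optimal" && res$delta > eps_slack))
      res <- lp_maximin(maps$W, maps$w0, lb, ub, hard_W = hw, hard_w0 = hw0,
                        eq_A = rbind(eqA, eqA0), eq_b = c(eqb, eqb0))
    if (res$status == "optimal" && res$delta > eps_slack) {
      phi <- 10^drop(L0 + LZ %*% res$z)
      es <- phi_eigen(phi, K)
      if (es$has_unstable_focus) {
        out$oscillatory_potential <- TRUE
        out$focus_point <- stats::setNames(10^res$z, znames)
        break
      }
    }
  }
  # (ii) seeded hit-and-run probes inside the region (additional evidence
  # when the scan is inconclusive)
  if (!out$oscillatory_potential && probe_budget > 0L) {
    probes <- hit_and_run(rbind(maps$W, hw), c(maps$w0, hw0), lb, ub,
                          vr$witness_log10, n = probe_budget, seed = seed,
                          eq_A = eqA0)
    for (i in seq_len(nrow(probes))) {
      phi <- 10^drop(L0 + LZ %*% probes[i, ])
      if (phi_eigen(phi, K)$has_unstable_focus) {
        out$oscillatory_potential <- TRUE
        out$focus_point <- stats::setNames(10^probes[i, ], znames)
        break
      }
    }
  }
  structure(out, class = "case_dynamics")
}

#' @export
print.case_dynamics <- function(x, ...) {
  cat(sprintf("Dynamics at witness: %s (%d positive eigenvalue(s)); oscillatory potential: %s\n",
              x$class, x$n_positive, x$oscillatory_potential))
  invisible(x)
}
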