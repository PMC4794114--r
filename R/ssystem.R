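# Compiled numeric view of a GMA system: per equation and sign, stacked
# matrices of log10 constants, parameter/independent exponents and dependent
# variable exponents.  z-coordinates are log10 of c(parameters, independent).
compile_gma <- function(system) {
  dep <- dependent_vars(system)
  znames <- c(system$parameters, system$independent)
  one_side <- function(terms) {
    nt <- length(terms)
    C <- vapply(terms, function(tm) log10(tm$const), 0)
    Z <- matrix(0, nt, length(znames), dimnames = list(NULL, znames))
    V <- matrix(0, nt, length(dep), dimnames = list(NULL, dep))
    for (j in seq_len(nt)) {
      tm <- terms[[j]]
      if (length(tm$params)) Z[j, names(tm$params)] <- tm$params
      iv <- intersect(names(tm$vars), dep)
      if (length(iv)) V[j, iv] <- tm$vars[iv]
      ii <- intersect(names(tm$vars), system$independent)
      if (length(ii)) Z[j, ii] <- Z[j, ii] + tm$vars[ii]
    }
    list(C = C, Z = Z, V = V)
  }
  eqs <- lapply(system$equations, function(eq)
    list(pos = one_side(eq$positive), neg = one_side(eq$negative)))
  list(eqs = eqs, dep = dep, znames = znames,
       dynamic_idx = match(system$dynamic, dep),
       auxiliary_idx = match(system$auxiliary, dep))
}

#' Log-linear steady state of an S-system
#'
#' Equating, per equation, the logarithm of the single positive term with the
#' logarithm of the single negative term yields a square linear system
#' `M y = b0 + Bz z` in the log10 dependent variables `y`, with a right side
#' affine in the log10 parameters (and independent variables) `z`.  Near
#' singular `M` (smallest singular value below `1e-10` times the largest) is
#' reported via `solvable = FALSE`, not as an error.
#'
#' @param ssystem a [gma_system()] with exactly one positive and one negative
#'   term in every equation (e.g. from [extract_ssystem()]).
#' @return An object of class `log_linear_steady_state`: list with `M`
#'   (coefficient matrix), `b0`, `Bz` (offset affine in z), `solvable`, and,
#'   when solvable, `Y0` and `YZ` such that `y = Y0 + YZ z`.
#' @examples
#' sys <- parse_model_file("X1' = a - b*X1")
#' st <- log_steady_state(sys)
#' st$Y0  # log10 X1* = log10 a - log10 b
#' @export
log_steady_state <- function(ssystem) {
  sig <- compute_system_signature(ssystem)
  if (any(sig$pairs != 1L))
    stop("log_steady_state requires an S-system (one positive and one ",
         "negative term per equation); use extract_ssystem() first")
  cm <- compile_gma(ssystem)
  n <- length(cm$dep)
  M <- matrix(0, n, n, dimnames = list(cm$dep, cm$dep))
  Bz <- matrix(0, n, length(cm$znames), dimnames = list(cm$dep, cm$znames))
  b0 <- numeric(n)
  for (i in seq_len(n)) {
    e <- cm$eqs[[i]]
    M[i, ] <- e$pos$V[1, ] - e$neg$V[1, ]
    Bz[i, ] <- e$neg$Z[1, ] - e$pos$Z[1, ]
    b0[i] <- e$neg$C[1] - e$pos$C[1]
  }
  sv <- svd(M, nu = 0, nv = 0)$d
  solvable <- n == 0L || (sv[1] > 0 && sv[n] >= 1e-10 * sv[1])
  out <- list(M = M, b0 = b0, Bz = Bz, solvable = solvable)
  if (solvable) {
    out$Y0 <- drop(solve(M, b0))
    out$YZ <- solve(M, Bz)
  }
  structure(out, class = "log_linear_steady_state")
}

#' @export
print.log_linear_steady_state <- function(x, ...) {
  cat(sprintf("Log-linear steady state over %d dependent variable(s); solvable: %s\n",
              nrow(x$M), x$solvable))
  invisible(x)
}

# Affine maps of a case: steady state y = Y0 + YZ z, dominance rows
# W z + w0 >= 0, and log10 turnover rates phi_i = T-_i / X_i for dynamic
# equations as l = L0 + LZ z.  Everything downstream (LP, rasterization,
# dynamics) is built from this object.
case_maps <- function(system, case, compiled = NULL) {
  sel <- case_pairs(system, case)
  cm <- if (is.null(compiled)) compile_gma(system) else compiled
  n <- length(cm$dep); nz <- length(cm$znames)
  M <- matrix(0, n, n, dimnames = list(cm$dep, cm$dep))
  Bz <- matrix(0, n, nz, dimnames = list(cm$dep, cm$znames))
  b0 <- numeric(n)
  for (i in seq_len(n)) {
    e <- cm$eqs[[i]]; p <- sel[i, 1]; q <- sel[i, 2]
    M[i, ] <- e$pos$V[p, ] - e$neg$V[q, ]
    Bz[i, ] <- e$neg$Z[q, ] - e$pos$Z[p, ]
    b0[i] <- e$neg$C[q] - e$pos$C[p]
  }
  sv <- svd(M, nu = 0, nv = 0)$d
  solvable <- sv[1] > 0 && sv[n] >= 1e-10 * sv[1]
  out <- list(sel = sel, compiled = cm, M = M, b0 = b0, Bz = Bz,
              solvable = solvable, znames = cm$znames, dep = cm$dep)
  if (!solvable) return(out)
  Y0 <- drop(solve(M, b0)); YZ <- solve(M, Bz)
  out$Y0 <- Y0; out$YZ <- YZ
  # dominance rows: log10(selected) - log10(competitor) at the steady state,
  # substituted to be affine in z only
  W <- NULL; w0 <- NULL; prov <- NULL
  for (i in seq_len(n)) {
    e <- cm$eqs[[i]]
    for (side in c("pos", "neg")) {
      s <- e[[side]]; k_sel <- sel[i, if (side == "pos") 1 else 2]
      for (k in seq_along(s$C)) {
        if (k == k_sel) next
        dZ <- s$Z[k_sel, ] - s$Z[k, ]
        dV <- s$V[k_sel, ] - s$V[k, ]
        W <- rbind(W, dZ + drop(dV %*% YZ))
        w0 <- c(w0, (s$C[k_sel] - s$C[k]) + sum(dV * Y0))
        prov <- rbind(prov, data.frame(equation = i, side = side, competitor = k,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(W)) {
    W <- matrix(0, 0, length(cm$znames), dimnames = list(NULL, cm$znames))
    w0 <- numeric(0)
    prov <- data.frame(equation = integer(0), side = character(0),
                       competitor = integer(0))
  } else {
    colnames(W) <- cm$znames
  }
  out$W <- W; out$w0 <- w0; out$provenance <- prov
  # turnover rates of dynamic equations: log10 phi_i = log10 T-_i - y_i
  di <- cm$dynamic_idx
  if (length(di)) {
    L0 <- numeric(length(di)); LZ <- matrix(0, length(di), nz,
                                            dimnames = list(cm$dep[di], cm$znames))
    for (j in seq_along(di)) {
      i <- di[j]; e <- cm$eqs[[i]]; q <- sel[i, 2]
      hv <- e$neg$V[q, ]; hv[i] <- hv[i] - 1  # subtract y_i
      L0[j] <- e$neg$C[q] + sum(hv * Y0)
      LZ[j, ] <- e$neg$Z[q, ] + drop(hv %*% YZ)
    }
    out$L0 <- L0; out$LZ <- LZ
  }
  # reduced net kinetic orders (auxiliaries eliminated): K = (G - H) over
  # dependent vars, reduced by the implicit function theorem on the aux block
  GH <- M  # rows: g_i - h_i over dependent variables
  ai <- cm$auxiliary_idx
  if (length(ai)) {
    A <- GH[di, di, drop = FALSE]; B <- GH[di, ai, drop = FALSE]
    C <- GH[ai, ai, drop = FALSE]; D <- GH[ai, di, drop = FALSE]
    svC <- svd(C, nu = 0, nv = 0)$d
    if (svC[length(svC)] < 1e-10 * max(svC, 1e-300)) {
      out$K_reduced <- NULL
      out$aux_singular <- TRUE
    } else {
      out$K_reduced <- A - B %*% solve(C, D)
      out$aux_singular <- FALSE
    }
  } else {
    out$K_reduced <- GH[di, di, drop = FALSE]
    out$aux_singular <- FALSE
  }
  out
}

#' Dominance conditions of a case
#'
#' For every non-selected term competing with the case's dominant term of the
#' same sign, one inequality `log10(dominant) - log10(competitor) >= 0`,
#' evaluated at the case's analytically determined S-system steady state so
#' that the dependent variables are eliminated: each row is affine in the
#' log10 parameters (and independent variables) only.  These rows are the
#' facets of the phenotype's polytope in log-parameter space.
#'
#' @param system a [gma_system()].
#' @param case case number, digit vector or `ssystem_case`.
#' @return An object of class `dominance_conditions`: list with `status`
#'   (`"ok"` or `"unresolvable"`), matrix `W`, offset `w0` (rows satisfy
#'   `W z + w0 >= 0`), provenance data frame, and the steady-state maps.
#' @export
dominance_conditions <- function(system, case) {
  maps <- case_maps(system, case)
  if (!maps$solvable)
    return(structure(list(status = "unresolvable", maps = maps,
                          bounds = system$bounds),
                     class = "dominance_conditions"))
  structure(list(status = "ok", W = maps$W, w0 = maps$w0,
                 provenance = maps$provenance, maps = maps,
                 bounds = system$bounds),
            class = "dominance_conditions")
}

#' @export
print.dominance_conditions <- function(x, ...) {
  if (x$status != "ok") cat("Dominance conditions: steady state unresolvable\n")
  else cat(sprintf("Dominance conditions: %d inequality row(s) over %d log10 coordinate(s)\n",
                   nrow(x$W), ncol(x$W)))
  invisible(x)
}

#' Fixed point of a case at a numeric parameter point
#'
#' Exponentiates the log-linear steady-state solution of the case's S-system.
#'
#' @param system a [gma_system()].
#' @param case case number, digit vector or `ssystem_case`.
#' @param params named vector of strictly positive parameter values (and
#'   independent-variable values, if any).
#' @return An object of class `fixed_point`: named concentrations of all
#'   dependent variables (dynamic and auxiliary), with the parameter point
#'   and case attached.
#' @export
fixed_point <- function(system, case, params) {
  maps <- case_maps(system, case)
  if (!maps$solvable) stop("case steady state is singular (unresolvable)")
  z <- log10_point(params, maps$znames)
  y <- drop(maps$Y0 + maps$YZ %*% z)
  names(y) <- maps$dep
  structure(list(concentrations = 10^y, log10 = y, params = params,
                 case = case), class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat("S-system fixed point:\n")
  print(signif(x$concentrations, 6))
  invisible(x)
}

# named linear-scale parameter vector -> log10 z vector in roster order
log10_point <- function(params, znames) {
  if (is.null(names(params))) stop("parameter point must be named")
  miss <- setdiff(znames, names(params))
  if (length(miss)) stop("missing parameter value(s): ", paste(miss, collapse = ", "))
  if (any(params[znames] <= 0)) stop("parameter values must be strictly positive")
  log10(as.numeric(params[znames]))
}
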