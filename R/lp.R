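# Dense two-phase primal simplex.  Small LPs only (tens of variables, a few
# hundred rows) but needs to be dependable: every phenotype test, witness,
# tolerance interval and ensemble in this package is one of these LPs.
# Dantzig pricing with a permanent switch to Bland's rule when the objective
# stalls (anti-cycling).

# min c'x  s.t.  A x <= b,  x >= 0
simplex_core <- function(cc, A, b, maxit = 20000L, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cc) == n, length(b) == m)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  slack <- diag(m)
  diag(slack)[neg] <- -1
  art_rows <- which(neg)
  nart <- length(art_rows)
  Art <- matrix(0, m, nart)
  if (nart) Art[cbind(art_rows, seq_len(nart))] <- 1
  Tb <- cbind(A, slack, Art, b)  # last column is the RHS
  ncols <- n + m + nart
  basis <- integer(m)
  basis[!neg] <- n + which(!neg)
  if (nart) basis[neg] <- n + m + seq_len(nart)

  pivot <- function(Tb, r, j) {
    Tb[r, ] <- Tb[r, ] / Tb[r, j]
    other <- setdiff(seq_len(nrow(Tb)), r)
    Tb[other, ] <- Tb[other, ] - outer(Tb[other, j], Tb[r, ])
    Tb
  }

  run_phase <- function(Tb, basis, obj, allow) {
    bland <- FALSE; stall <- 0L; last <- Inf
    for (it in seq_len(maxit)) {
      red <- obj - drop(crossprod(obj[basis], Tb[, seq_len(ncols), drop = FALSE]))
      red[!allow] <- 0
      cand <- which(red < -tol)
      if (!length(cand))
        return(list(status = "optimal", Tb = Tb, basis = basis))
      j <- if (bland) cand[1] else cand[which.min(red[cand])]
      col <- Tb[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(status = "unbounded", Tb = Tb, basis = basis))
      ratio <- Tb[pos, ncols + 1L] / col[pos]
      r <- pos[ratio <= min(ratio) + tol]
      r <- r[which.min(basis[r])]
      Tb <- pivot(Tb, r, j)
      basis[r] <- j
      val <- drop(crossprod(obj[basis], Tb[, ncols + 1L]))
      if (val < last - tol) { last <- val; stall <- 0L } else stall <- stall + 1L
      if (stall > 2L * (m + n)) bland <- TRUE
    }
    list(status = "maxiter", Tb = Tb, basis = basis)
  }

  allow <- rep(TRUE, ncols)
  if (nart) {
    obj1 <- c(rep(0, n + m), rep(1, nart))
    ph1 <- run_phase(Tb, basis, obj1, allow)
    if (ph1$status != "optimal") return(list(status = ph1$status))
    Tb <- ph1$Tb; basis <- ph1$basis
    val1 <- drop(crossprod(obj1[basis], Tb[, ncols + 1L]))
    if (val1 > 1e-7) return(list(status = "infeasible", phase1 = val1))
    # drive any basic artificial (at value 0) out of the basis if possible
    for (r in which(basis > n + m)) {
      row <- Tb[r, seq_len(n + m)]
      j <- which(abs(row) > tol)
      j <- j[allow[j]][1]
      if (!is.na(j)) { Tb <- pivot(Tb, r, j); basis[r] <- j }
    }
    allow[(n + m + 1L):ncols] <- FALSE
  }
  obj2 <- c(cc, rep(0, m), rep(0, nart))
  ph2 <- run_phase(Tb, basis, obj2, allow)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  Tb <- ph2$Tb; basis <- ph2$basis
  x <- numeric(n)
  keep <- basis <= n
  x[basis[keep]] <- Tb[keep, ncols + 1L]
  list(status = "optimal", x = x, value = sum(cc * x))
}

#' Solve a small dense linear program
#'
#' Minimizes (or maximizes) `c'x` subject to `A x <= b`, optional equality
#' rows `Aeq x = beq`, and finite bounds `lb <= x <= ub`, using the package's
#' two-phase simplex.  Intended for the modest problem sizes that arise in
#' dominance analysis; bounds must be finite.
#'
#' @param cc objective coefficient vector.
#' @param A,b inequality constraints `A x <= b` (may be `NULL`).
#' @param Aeq,beq equality constraints (may be `NULL`).
#' @param lb,ub finite bounds, recycled to `length(cc)`.
#' @param maximize maximize instead of minimize.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxiter"`), and for optimal solutions `x` and `value`.
#' @export
solve_lp <- function(cc, A = NULL, b = NULL, Aeq = NULL, beq = NULL,
                     lb = -1e6, ub = 1e6, maximize = FALSE) {
  n <- length(cc)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) stop("bounds must be finite")
  if (any(lb > ub)) return(list(status = "infeasible"))
  if (is.null(A)) { A <- matrix(0, 0, n); b <- numeric(0) }
  A <- as.matrix(A)
  if (!is.null(Aeq)) {
    Aeq <- as.matrix(Aeq)
    A <- rbind(A, Aeq, -Aeq)
    b <- c(b, beq, -beq)
  }
  # shift to y = x - lb >= 0; upper bounds become rows
  bshift <- b - drop(A %*% lb)
  A2 <- rbind(A, diag(n))
  b2 <- c(bshift, ub - lb)
  cc2 <- if (maximize) -cc else cc
  res <- simplex_core(cc2, A2, b2)
  if (res$status != "optimal") return(res)
  x <- res$x + lb
  list(status = "optimal", x = x, value = sum(cc * x))
}

# Maximal-minimum-slack LP: maximize delta such that
#   W z + w0 >= delta        (dominance rows)
#   lb + delta <= z <= ub - delta   (interior-of-box rows)
#   hard_W z + hard_w0 >= 0  (hard extra constraints, no slack)
#   eq_A z = eq_b            (equality constraints)
# The optimum is often degenerate (a whole face attains the maximal
# slack); a second stage selects a canonical point on that face by
# maximizing the total dominance margin, so witnesses are reproducible
# and sit deep in the region also in an average sense.
# Returns z (the slack-maximizing witness) and delta.
lp_maximin <- function(W, w0, lb, ub, hard_W = NULL, hard_w0 = NULL,
                       eq_A = NULL, eq_b = NULL) {
  p <- length(lb)
  if (is.null(W)) { W <- matrix(0, 0, p); w0 <- numeric(0) }
  m <- nrow(W)
  scale <- pmax(abs(lb), abs(ub), 1)
  Dlim <- 1 + max(c(0, abs(w0) + drop(abs(W) %*% scale)), (ub - lb) / 2)
  # variables x = (z, delta)
  A <- rbind(
    if (m) cbind(-W, 1),
    cbind(-diag(p), 1),
    cbind(diag(p), 1),
    if (!is.null(hard_W)) cbind(-hard_W, 0)
  )
  b <- c(if (m) w0, -lb, ub, if (!is.null(hard_W)) hard_w0)
  Aeq <- if (!is.null(eq_A)) cbind(eq_A, 0)
  cc <- c(rep(0, p), 1)
  res <- solve_lp(cc, A, b, Aeq = Aeq, beq = eq_b,
                  lb = c(lb, -Dlim), ub = c(ub, Dlim), maximize = TRUE)
  if (res$status != "optimal") return(list(status = res$status))
  delta <- res$x[p + 1L]
  z <- res$x[seq_len(p)]
  if (m) {
    # stage 2: on the optimal face (slack fixed at delta, with a small
    # tolerance so the face is not cut away numerically), maximize the sum
    # of the dominance margins
    A2 <- rbind(A, c(rep(0, p), -1))
    b2 <- c(b, -(delta - 1e-9))
    cc2 <- c(colSums(W), 0)
    res2 <- solve_lp(cc2, A2, b2, Aeq = Aeq, beq = eq_b,
                     lb = c(lb, -Dlim), ub = c(ub, Dlim), maximize = TRUE)
    if (res2$status == "optimal") {
      z <- res2$x[seq_len(p)]
      # report the slack achieved at the returned witness
      delta <- min(drop(W %*% z) + w0, z - lb, ub - z)
    }
  }
  names(z) <- colnames(W) %||% names(lb)
  list(status = "optimal", z = z, delta = delta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
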