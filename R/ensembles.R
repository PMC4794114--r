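# Joint LP over an ensemble of cases: one copy of the axis coordinates per
# case, a single shared copy of every other parameter, maximize the minimum
# slack across all cases' dominance rows (and box interiority).
joint_ensemble_lp <- function(system, cases, axes, bounds, constraints = NULL,
                              order_rows = NULL, eps_slack = 1e-6) {
  znames <- colnames(system$bounds)
  stopifnot(all(axes %in% znames), !anyDuplicated(axes))
  if (is.null(bounds)) bounds <- system$bounds
  shared <- setdiff(znames, axes)
  k <- length(cases); na <- length(axes)
  compiled <- compile_gma(system)
  sys_sig <- compute_system_signature(system)
  maps <- lapply(cases, function(n)
    case_maps(system, number_to_signature(n, sys_sig), compiled))
  bad <- vapply(maps, function(m) !m$solvable, TRUE)
  if (any(bad)) stop("unresolvable case(s): ", paste(cases[bad], collapse = ", "))
  p <- length(shared) + k * na
  vnames <- c(shared, unlist(lapply(seq_len(k), function(i)
    paste0(axes, "#", cases[i]))))
  W <- NULL; w0 <- NULL
  for (i in seq_len(k)) {
    m <- maps[[i]]
    if (!nrow(m$W)) next
    Wi <- matrix(0, nrow(m$W), p, dimnames = list(NULL, vnames))
    Wi[, shared] <- m$W[, shared, drop = FALSE]
    Wi[, paste0(axes, "#", cases[i])] <- m$W[, axes, drop = FALSE]
    W <- rbind(W, Wi); w0 <- c(w0, m$w0)
  }
  lb <- c(bounds["lb", shared], rep(bounds["lb", axes], k))
  ub <- c(bounds["ub", shared], rep(bounds["ub", axes], k))
  names(lb) <- names(ub) <- vnames
  hw <- hw0 <- eqA <- eqb <- NULL
  if (!is.null(constraints)) {
    if (!is.null(constraints$W)) {
      if (length(intersect(colnames(constraints$W), axes)))
        stop("ensemble constraints may only involve shared (non-axis) parameters")
      hw <- expand_rows(constraints$W, vnames); hw0 <- constraints$w0
    }
    if (!is.null(constraints$eq_A)) {
      if (length(intersect(colnames(constraints$eq_A), axes)))
        stop("ensemble constraints may only involve shared (non-axis) parameters")
      eqA <- expand_rows(constraints$eq_A, vnames); eqb <- constraints$eq_b
    }
  }
  if (!is.null(order_rows)) {
    hw <- rbind(hw, expand_rows(order_rows$W, vnames))
    hw0 <- c(hw0, order_rows$w0)
  }
  res <- lp_maximin(W, w0, lb, ub, hard_W = hw, hard_w0 = hw0,
                    eq_A = eqA, eq_b = eqb)
  feasible <- res$status == "optimal" && res$delta > eps_slack
  out <- list(cases = cases, axes = axes, feasible = feasible,
              status = if (feasible) "feasible" else "infeasible")
  if (res$status == "optimal") {
    out$slack <- res$delta
    zsh <- res$z[shared]
    out$shared_log10 <- zsh
    out$shared <- 10^zsh
    ax <- matrix(res$z[-seq_along(shared)], nrow = k, byrow = TRUE,
                 dimnames = list(as.character(cases), axes))
    out$axis_log10 <- ax
    out$axis <- 10^ax
  }
  structure(out, class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("Ensemble of case(s) %s in axes (%s): %s",
              paste(x$cases, collapse = ", "), paste(x$axes, collapse = ", "),
              x$status))
  if (!is.null(x$slack)) cat(sprintf(" (joint slack %.4g)", x$slack))
  cat("\n")
  invisible(x)
}

#' Co-localize an ensemble of phenotypes in one slice
#'
#' Finds a single assignment of all non-axis parameters, plus per-case axis
#' coordinates, such that every requested case's dominance conditions hold
#' simultaneously -- i.e. all requested phenotypes appear in the same
#' two-dimensional slice of design space.  Solved as one joint LP
#' maximizing the minimum slack across all cases.
#'
#' @param system a [gma_system()].
#' @param repertoire its [enumerate_repertoire()] result.
#' @param cases case numbers to co-localize (must be valid).
#' @param axes the two axis parameter names.
#' @param bounds optional log10 bounds (default: the system's).
#' @param constraints optional [linear_constraints()] on shared parameters.
#' @param eps_slack strict-slack threshold.
#' @return An `ensemble_result` with the shared parameters, per-case axis
#'   coordinates and joint slack; `feasible = FALSE` when the ensemble
#'   cannot be realized in this slice.
#' @export
co_localize <- function(system, repertoire, cases, axes, bounds = NULL,
                        constraints = NULL, eps_slack = 1e-6) {
  stopifnot(length(axes) == 2L)
  notvalid <- setdiff(cases, repertoire$valid_cases)
  if (length(notvalid))
    stop("case(s) not individually valid: ", paste(notvalid, collapse = ", "))
  joint_ensemble_lp(system, cases, axes, bounds, constraints,
                    eps_slack = eps_slack)
}

#' Maximum co-visualizable subset of phenotypes
#'
#' Exact search for a maximum-cardinality subset of the valid cases that can
#' be co-localized in a slice with the given axes.  Subsets are tested in
#' decreasing size, lexicographic order within a size; joint feasibility is
#' monotone under subset inclusion, so any candidate containing a known
#' infeasible subset (including the precomputed infeasible pairs) is pruned
#' without an LP.  The first feasible subset found is maximum and, by the
#' enumeration order, lexicographically smallest among ties.
#'
#' @inheritParams co_localize
#' @param verbose print progress.
#' @return List with `subset` (case numbers) and `ensemble`
#'   (the `ensemble_result`).
#' @export
maximal_coexistent_subset <- function(system, repertoire, axes, bounds = NULL,
                                      constraints = NULL, eps_slack = 1e-6,
                                      verbose = FALSE) {
  valid <- repertoire$valid_cases
  stopifnot(length(valid) >= 1L)
  nv <- length(valid)
  test <- function(subset)
    joint_ensemble_lp(system, valid[subset], axes, bounds, constraints,
                      eps_slack = eps_slack)
  # bitmask helpers over indices 1..nv
  mask_of <- function(idx) sum(bitwShiftL(1, idx - 1L))
  infeasible <- integer(0)
  # pairwise prefilter
  if (nv >= 2L) {
    prs <- utils::combn(nv, 2L)
    for (c_ in seq_len(ncol(prs))) {
      if (!test(prs[, c_])$feasible)
        infeasible <- c(infeasible, mask_of(prs[, c_]))
    }
    if (verbose) message(length(infeasible), " infeasible pair(s)")
  }
  for (k in rev(seq_len(nv))) {
    subs <- utils::combn(nv, k)
    for (c_ in seq_len(ncol(subs))) {
      idx <- subs[, c_]
      mk <- mask_of(idx)
      if (length(infeasible) &&
          any(bitwAnd(mk, infeasible) == infeasible)) next
      ens <- test(idx)
      if (ens$feasible) {
        if (verbose) message("maximum subset size ", k)
        return(list(subset = valid[idx], ensemble = ens))
      }
      infeasible <- c(infeasible, mk)
    }
  }
  stop("no single case is realizable; repertoire and bounds disagree")
}

#' Ordered ensemble of phenotypes along one axis
#'
#' Co-localizes the requested cases with a single free axis coordinate per
#' case and enforces the requested order along that axis: each case's
#' coordinate must lie at least `margin` log10 units below the next one's.
#'
#' @inheritParams co_localize
#' @param cases case numbers in the requested order along the axis.
#' @param axis single axis parameter name.
#' @param margin minimal log10 separation between consecutive cases.
#' @return An `ensemble_result`; `feasible = FALSE` when the order cannot be
#'   realized on this axis.
#' @export
ordered_ensemble <- function(system, repertoire, cases, axis, bounds = NULL,
                             constraints = NULL, margin = 0.5,
                             eps_slack = 1e-6) {
  stopifnot(length(axis) == 1L)
  notvalid <- setdiff(cases, repertoire$valid_cases)
  if (length(notvalid))
    stop("case(s) not individually valid: ", paste(notvalid, collapse = ", "))
  k <- length(cases)
  order_rows <- NULL
  if (k >= 2L) {
    vn <- paste0(axis, "#", cases)
    W <- matrix(0, k - 1L, k, dimnames = list(NULL, vn))
    for (j in seq_len(k - 1L)) { W[j, j] <- -1; W[j, j + 1L] <- 1 }
    order_rows <- list(W = W, w0 = rep(-margin, k - 1L))
  }
  joint_ensemble_lp(system, cases, axis, bounds, constraints,
                    order_rows = order_rows, eps_slack = eps_slack)
}
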