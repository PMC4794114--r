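#' Extra linear constraints in log-parameter space
#'
#' Bundles hard inequality rows `W z + w0 >= 0` and equality rows
#' `eq_A z = eq_b` over the log10 parameter coordinates `z`.  Used to impose
#' e.g. fold-change orderings, fixed parameter values, or matched time
#' scales on witness generation and ensembles.  Hard rows must hold but do
#' not take part in slack maximization.
#'
#' @param W,w0 inequality rows (matrix with named columns, offset vector).
#' @param eq_A,eq_b equality rows.
#' @return An object of class `linear_constraints`.
#' @export
linear_constraints <- function(W = NULL, w0 = NULL, eq_A = NULL, eq_b = NULL) {
  if (!is.null(W)) {
    W <- as.matrix(W)
    if (is.null(colnames(W))) stop("constraint rows need parameter names as colnames")
    stopifnot(length(w0) == nrow(W))
  }
  if (!is.null(eq_A)) {
    eq_A <- as.matrix(eq_A)
    if (is.null(colnames(eq_A))) stop("constraint rows need parameter names as colnames")
    stopifnot(length(eq_b) == nrow(eq_A))
  }
  structure(list(W = W, w0 = w0, eq_A = eq_A, eq_b = eq_b),
            class = "linear_constraints")
}

# expand constraint rows onto the full z roster (absent names get 0)
expand_rows <- function(M, znames) {
  if (is.null(M)) return(NULL)
  out <- matrix(0, nrow(M), length(znames), dimnames = list(NULL, znames))
  bad <- setdiff(colnames(M), znames)
  if (length(bad)) stop("constraint references unknown parameter(s): ",
                        paste(bad, collapse = ", "))
  out[, colnames(M)] <- M
  out
}

#' Test validity of a phenotype by linear programming
#'
#' Solves `maximize delta` subject to every dominance row exceeding `delta`
#' and the log10 parameters lying at least `delta` inside their bounds.  The
#' case is valid iff the optimal slack exceeds `eps_slack`: validity means a
#' nonempty interior, boundary-only cases are invalid.  The optimizer is the
#' slack-maximizing witness, an automatically determined parameter set
#' realizing the phenotype.
#'
#' @param conds a [dominance_conditions()] object.
#' @param bounds two-row (`lb`, `ub`) log10 bounds matrix over parameters;
#'   defaults to the bounds stored on the system.
#' @param eps_slack strict-slack validity threshold in log10 units.
#' @param constraints optional [linear_constraints()].
#' @return An object of class `validity_result`: `valid`, `status` (one of
#'   `"valid"`, `"infeasible"`, `"unresolvable"`), `slack`, and witness
#'   vectors `witness_log10` / `witness` (linear scale).
#' @export
assess_validity <- function(conds, bounds = NULL, eps_slack = 1e-6,
                            constraints = NULL) {
  stopifnot(inherits(conds, "dominance_conditions"))
  if (conds$status == "unresolvable")
    return(structure(list(valid = FALSE, status = "unresolvable",
                          slack = NA_real_), class = "validity_result"))
  znames <- colnames(conds$W)
  if (is.null(bounds)) bounds <- conds$bounds
  if (is.null(bounds)) stop("no parameter bounds available")
  lb <- bounds["lb", znames]; ub <- bounds["ub", znames]
  hw <- hw0 <- eqA <- eqb <- NULL
  if (!is.null(constraints)) {
    hw <- expand_rows(constraints$W, znames); hw0 <- constraints$w0
    eqA <- expand_rows(constraints$eq_A, znames); eqb <- constraints$eq_b
  }
  res <- lp_maximin(conds$W, conds$w0, lb, ub, hard_W = hw, hard_w0 = hw0,
                    eq_A = eqA, eq_b = eqb)
  if (res$status != "optimal")
    return(structure(list(valid = FALSE, status = "infeasible",
                          slack = -Inf, diagnostic = res$status),
                     class = "validity_result"))
  wl <- res$z
  names(wl) <- znames
  structure(list(valid = res$delta > eps_slack,
                 status = if (res$delta > eps_slack) "valid" else "infeasible",
                 slack = res$delta, witness_log10 = wl, witness = 10^wl),
            class = "validity_result")
}

#' @export
print.validity_result <- function(x, ...) {
  cat(sprintf("Phenotype validity: %s (slack %.4g log10 units)\n", x$status, x$slack))
  invisible(x)
}

#' Enumerate the phenotypic repertoire of a GMA system
#'
#' Iterates over every potential case (dominant-term selection), builds its
#' dominance conditions and tests validity by slack-maximizing linear
#' programming within the log10 parameter bounds.  The result collects, per
#' case, the status, maximal slack and witness; the phenotypic fraction is
#' the number of valid cases over the number of potential cases.
#'
#' @param system a [gma_system()].
#' @param bounds optional log10 bounds matrix (default: the system's).
#' @param eps_slack strict-slack validity threshold.
#' @param constraints optional [linear_constraints()] applied to every case.
#' @return An object of class `phenotypic_repertoire`: a list with `table`
#'   (data frame: case_number, signature, status, slack), `results` (list of
#'   `validity_result`), `valid_cases` (sorted case numbers), `system`,
#'   `bounds`.
#' @examples
#' rep <- enumerate_repertoire(relaxation_oscillator()$system)
#' rep$valid_cases
#' @export
enumerate_repertoire <- function(system, bounds = NULL, eps_slack = 1e-6,
                                 constraints = NULL) {
  stopifnot(inherits(system, "gma_system"))
  if (is.null(bounds)) bounds <- system$bounds
  sys_sig <- compute_system_signature(system)
  ncases <- total_case_count(sys_sig)
  compiled <- compile_gma(system)
  results <- vector("list", ncases)
  sigs <- character(ncases)
  for (n in seq_len(ncases)) {
    sig <- number_to_signature(n, sys_sig)
    sigs[n] <- sig$flat
    maps <- case_maps(system, sig, compiled)
    conds <- if (!maps$solvable)
      structure(list(status = "unresolvable", maps = maps),
                class = "dominance_conditions")
    else
      structure(list(status = "ok", W = maps$W, w0 = maps$w0,
                     provenance = maps$provenance, maps = maps),
                class = "dominance_conditions")
    results[[n]] <- assess_validity(conds, bounds = bounds,
                                    eps_slack = eps_slack,
                                    constraints = constraints)
  }
  tab <- data.frame(
    case_number = seq_len(ncases),
    signature = sigs,
    status = vapply(results, `[[`, "", "status"),
    slack = vapply(results, `[[`, 0, "slack"),
    stringsAsFactors = FALSE)
  structure(list(table = tab, results = results,
                 valid_cases = tab$case_number[tab$status == "valid"],
                 system = system, bounds = bounds, eps_slack = eps_slack),
            class = "phenotypic_repertoire")
}

#' @export
print.phenotypic_repertoire <- function(x, ...) {
  n <- nrow(x$table)
  cat(sprintf("Phenotypic repertoire: %d valid of %d potential phenotypes\n",
              length(x$valid_cases), n))
  if (length(x$valid_cases))
    cat("  valid cases:", paste(x$valid_cases, collapse = ", "), "\n")
  invisible(x)
}

#' Slack-maximizing interior parameter point of a valid case
#'
#' Returns the parameter set automatically determined for a phenotype: the
#' witness maximizing the minimal margin of the case's dominance rows (and
#' distance to the bounds), optionally under extra constraints.  Errors
#' distinguish an invalid case from constraints that exclude the region.
#'
#' @param system a [gma_system()].
#' @param case case number, digit vector or `ssystem_case`.
#' @param bounds optional log10 bounds (default: the system's).
#' @param constraints optional [linear_constraints()].
#' @param eps_slack strict-slack threshold.
#' @return List with `params` (named, linear scale), `log10` (named log10
#'   vector) and `slack`.
#' @export
interior_parameter_point <- function(system, case, bounds = NULL,
                                     constraints = NULL, eps_slack = 1e-6) {
  conds <- dominance_conditions(system, case)
  if (conds$status == "unresolvable") stop("case steady state is unresolvable")
  if (is.null(bounds)) bounds <- system$bounds
  res <- assess_validity(conds, bounds, eps_slack, constraints)
  if (!res$valid) {
    if (is.null(constraints)) stop("case is not valid within the given bounds")
    base <- assess_validity(conds, bounds, eps_slack)
    if (base$valid)
      stop("constraints exclude the case's region (case itself is valid)")
    stop("case is not valid within the given bounds")
  }
  list(params = res$witness, log10 = res$witness_log10, slack = res$slack)
}

#' Per-parameter validity tolerances around a point
#'
#' For each parameter in turn, all others held fixed at `point`, computes the
#' maximal log10 interval over which the case's dominance rows remain
#' satisfied (the dominance rows are affine, so each row contributes a
#' half-line; the tolerance is the intersection, clipped to the bounds).
#'
#' @param system a [gma_system()].
#' @param case case number, digit vector or `ssystem_case`.
#' @param point named parameter vector (linear scale) valid for the case.
#' @return Two-row matrix (`lb`, `ub`) of log10 interval endpoints per
#'   parameter.
#' @export
parameter_tolerances <- function(system, case, point) {
  conds <- dominance_conditions(system, case)
  if (conds$status == "unresolvable") stop("case steady state is unresolvable")
  znames <- colnames(conds$W)
  z <- log10_point(point, znames)
  vals <- if (nrow(conds$W)) drop(conds$W %*% z + conds$w0) else numeric(0)
  if (length(vals) && min(vals) < 0)
    stop("point does not satisfy the case's dominance conditions")
  bounds <- system$bounds[, znames, drop = FALSE]
  out <- bounds
  for (j in seq_along(znames)) {
    lo <- bounds["lb", j]; hi <- bounds["ub", j]
    if (nrow(conds$W)) {
      wj <- conds$W[, j]
      rest <- vals - wj * z[j]           # row value with z_j removed
      pos <- wj > 1e-12; ne <- wj < -1e-12
      if (any(pos)) lo <- max(lo, max(-rest[pos] / wj[pos]))
      if (any(ne)) hi <- min(hi, min(-rest[ne] / wj[ne]))
    }
    out["lb", j] <- lo; out["ub", j] <- hi
  }
  out
}
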