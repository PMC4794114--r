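#' Specification for a random GMA fixture
#'
#' Controls the seeded generator of small synthetic GMA systems used to
#' exercise enumeration, LP validity and dynamics against independent
#' oracles.  Two structural classes are available:
#'
#' * `"cascade"` (default): the regulatory dependency graph is acyclic --
#'   each variable's production terms involve only upstream variables (and
#'   binding polynomials over upstream variables), and every negative term
#'   is own-variable turnover.  For this class the dominant-term case at
#'   any parameter point can be chosen equation by equation going
#'   downstream, so it is always self-consistent: the valid regions tile
#'   the sampled parameter box.
#' * `"feedback"`: production terms may involve any other variable, so
#'   regulatory loops arise.  Richer dynamics, but dominance can cycle
#'   (a point may belong to no valid region) and singular (unresolvable)
#'   cases occur; coverage is not guaranteed for this class.
#'
#' @param n_dynamic number of dynamic variables.
#' @param n_auxiliary number of auxiliary (algebraic) variables.
#' @param term_range length-2 integer range for per-sign term counts.
#' @param exponents candidate nonzero exponent values.
#' @param sparsity probability that a candidate variable enters a term.
#' @param structure `"cascade"` or `"feedback"`.
#' @param seed integer seed; generation is deterministic per seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_dynamic = 2L, n_auxiliary = 0L,
                         term_range = c(1L, 3L),
                         exponents = c(-2, -1, 1, 2), sparsity = 0.5,
                         structure = c("cascade", "feedback"), seed = 1L) {
  structure <- match.arg(structure)
  stopifnot(n_dynamic >= 1L, n_auxiliary >= 0L, term_range[1] >= 1L,
            term_range[2] >= term_range[1], length(exponents) >= 1L,
            sparsity > 0, sparsity <= 1)
  if (structure == "cascade" && n_auxiliary > 0L && n_dynamic < 2L)
    stop("cascade fixtures need n_dynamic >= 2 to host auxiliary variables")
  base::structure(list(n_dynamic = as.integer(n_dynamic),
                       n_auxiliary = as.integer(n_auxiliary),
                       term_range = as.integer(term_range),
                       exponents = as.numeric(exponents),
                       sparsity = sparsity, structure = structure,
                       seed = as.integer(seed)),
                  class = "fixture_spec")
}

#' Generate a random GMA fixture system
#'
#' @param spec a [fixture_spec()].
#' @return A well-formed [gma_system()]; identical across calls with the
#'   same spec (seed included).  All rate constants are distinct
#'   parameters.
#' @export
random_gma_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  rs <- local_rng(spec$seed)
  nd <- spec$n_dynamic; na <- spec$n_auxiliary
  cascade <- spec$structure == "cascade"
  dynv <- paste0("X", seq_len(nd))
  auxv <- if (na) paste0("d", seq_len(na)) else character(0)
  pidx <- 0L
  next_param <- function() { pidx <<- pidx + 1L; paste0("p", pidx) }
  rint <- function(lo, hi) as.integer(lo + floor(rs$unif(1) * (hi - lo + 1L)))
  pick <- function(v) v[rint(1L, length(v))]
  rand_expos <- function(vars) {
    e <- numeric(0)
    for (v in vars) if (rs$unif(1) < spec$sparsity)
      e[v] <- pick(spec$exponents)
    e
  }
  # in a cascade, auxiliary k spans X1..X_{aux_max[k]} and may only appear
  # in equations strictly downstream of all its variables
  aux_max <- if (na) vapply(seq_len(na), function(k)
    rint(1L, max(1L, nd - 1L)), 1L) else integer(0)
  eqs <- list()
  for (i in seq_len(nd)) {
    prod_vars <- if (cascade) c(dynv[seq_len(i - 1L)], auxv[aux_max < i])
    else c(dynv[-i], auxv)
    P <- rint(spec$term_range[1], spec$term_range[2])
    N <- rint(spec$term_range[1], spec$term_range[2])
    pos <- lapply(seq_len(P), function(j)
      power_law_term(params = stats::setNames(1, next_param()),
                     vars = rand_expos(prod_vars)))
    neg <- lapply(seq_len(N), function(j) {
      vars <- if (cascade) numeric(0) else rand_expos(dynv[-i])
      vars[dynv[i]] <- pick(c(1, 2))  # own-variable turnover
      power_law_term(params = stats::setNames(1, next_param()), vars = vars)
    })
    eqs[[i]] <- gma_equation(dynv[i], pos, neg, "differential")
  }
  for (k in seq_len(na)) {
    span <- if (cascade) dynv[seq_len(aux_max[k])] else dynv
    Tn <- rint(max(2L, spec$term_range[1]), max(2L, spec$term_range[2]))
    pos <- c(list(power_law_term(1)),
             lapply(seq_len(Tn - 1L), function(j) {
               vars <- rand_expos(span)
               if (!length(vars)) vars <- stats::setNames(pick(c(1, 2)), pick(span))
               power_law_term(params = stats::setNames(1, next_param()), vars = vars)
             }))
    eqs[[nd + k]] <- gma_equation(
      auxv[k], pos, list(power_law_term(1, vars = stats::setNames(1, auxv[k]))),
      "algebraic")
  }
  gma_system(eqs)
}

#' Sampling oracle for phenotype validity
#'
#' Draws `n_samples` log-uniform parameter points within the bounds and
#' checks the case's dominance conditions by direct evaluation at each
#' point's S-system steady state.  Returns `TRUE` iff some sample satisfies
#' all conditions strictly.  One-sided by construction: `TRUE` implies the
#' case is valid (the sample is a witness); `FALSE` proves nothing.  Used
#' as an independent cross-check of the LP-based [assess_validity()].
#'
#' @param system a [gma_system()].
#' @param case case number, digit vector or `ssystem_case`.
#' @param bounds optional log10 bounds (default: the system's).
#' @param n_samples number of sampled points.
#' @param seed integer seed.
#' @return Logical scalar.
#' @export
sampling_oracle_validity <- function(system, case, bounds = NULL,
                                     n_samples = 1e4, seed = 1L) {
  maps <- case_maps(system, case)
  if (!maps$solvable) return(FALSE)
  if (is.null(bounds)) bounds <- system$bounds
  znames <- maps$znames
  lb <- bounds["lb", znames]; ub <- bounds["ub", znames]
  if (!nrow(maps$W)) return(TRUE)
  rs <- local_rng(seed)
  chunk <- 2000L
  left <- n_samples
  while (left > 0) {
    m <- min(chunk, left); left <- left - m
    U <- matrix(rs$unif(m * length(lb)), m, length(lb))
    Z <- sweep(sweep(U, 2, ub - lb, `*`), 2, lb, `+`)
    vals <- Z %*% t(maps$W) + matrix(maps$w0, m, length(maps$w0), byrow = TRUE)
    rmin <- do.call(pmin, lapply(seq_len(ncol(vals)), function(j) vals[, j]))
    if (any(rmin > 0)) return(TRUE)
  }
  FALSE
}
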