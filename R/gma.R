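#' @keywords internal
"_PACKAGE"

#' Power-law term
#'
#' A single term of a GMA rate law: a positive numeric constant multiplied by
#' a product of parameters and variables raised to (possibly negative,
#' possibly fractional) exponents, i.e.
#' `const * prod(param_j ^ e_j) * prod(var_k ^ f_k)`.
#'
#' @param const strictly positive numeric multiplier.
#' @param params named numeric vector of parameter exponents (absent = 0).
#' @param vars named numeric vector of variable exponents (absent = 0).
#' @return An object of class `power_law_term`.
#' @examples
#' # a1 * rA1 * (X2/KA1)^2 * d1^-1
#' power_law_term(params = c(a1 = 1, rA1 = 1, KA1 = -2), vars = c(X2 = 2, d1 = -1))
#' @export
power_law_term <- function(const = 1, params = numeric(0), vars = numeric(0)) {
  if (!is.numeric(const) || length(const) != 1L || !is.finite(const) || const <= 0)
    stop("term constant must be a single strictly positive number")
  params <- params[params != 0]
  vars <- vars[vars != 0]
  if (length(params) && (is.null(names(params)) || any(!nzchar(names(params)))))
    stop("parameter exponents must be named")
  if (length(vars) && (is.null(names(vars)) || any(!nzchar(names(vars)))))
    stop("variable exponents must be named")
  structure(list(const = as.numeric(const),
                 params = params, vars = vars),
            class = "power_law_term")
}

#' GMA equation
#'
#' One equation of a GMA system: either a differential equation
#' `dX/dt = sum(positive) - sum(negative)` or an algebraic constraint
#' `0 = sum(positive) - sum(negative)` defining an auxiliary variable.  By
#' convention an algebraic equation carries its target (auxiliary) variable
#' as the single negative term with exponent 1.
#'
#' @param target name of the dependent variable the equation determines.
#' @param positive,negative non-empty lists of [power_law_term()]s.
#' @param kind `"differential"` or `"algebraic"`.
#' @return An object of class `gma_equation`.
#' @export
gma_equation <- function(target, positive, negative, kind = c("differential", "algebraic")) {
  kind <- match.arg(kind)
  if (!is.character(target) || length(target) != 1L || !nzchar(target))
    stop("target must be a single variable name")
  as_terms <- function(x) {
    if (inherits(x, "power_law_term")) x <- list(x)
    if (!is.list(x) || !length(x) || !all(vapply(x, inherits, TRUE, "power_law_term")))
      stop("positive/negative must be non-empty lists of power_law_term")
    x
  }
  positive <- as_terms(positive)
  negative <- as_terms(negative)
  if (kind == "algebraic") {
    hits <- vapply(negative, function(tm) identical(unname(tm$vars[target]), 1) &&
                     length(tm$vars) == 1L && length(tm$params) == 0L &&
                     tm$const == 1, TRUE)
    if (sum(hits) != 1L || length(negative) != 1L)
      stop("algebraic equation must have the auxiliary variable as its single ",
           "negative term with exponent 1")
  }
  structure(list(target = target, kind = kind,
                 positive = positive, negative = negative),
            class = "gma_equation")
}

#' GMA system
#'
#' An ordered set of differential and algebraic [gma_equation()]s over named
#' dynamic, auxiliary and independent variables.  Equation order is fixed and
#' determines the digit order of the system signature.  Every parameter has
#' log10 bounds (default \eqn{\pm 6} decades) used by the linear programs.
#'
#' @param equations list of [gma_equation()]s, one per dependent variable.
#' @param independent character vector of independent (input) variable names.
#' @param bounds optional two-row matrix (rows `lb`, `ub`) of log10 bounds
#'   with one column per parameter (and independent variable, if any);
#'   missing columns default to `default_bounds`.
#' @param default_bounds length-2 numeric, default log10 bounds.
#' @return An object of class `gma_system`.
#' @seealso [parse_model_file()], [compute_system_signature()]
#' @export
gma_system <- function(equations, independent = character(0), bounds = NULL,
                       default_bounds = c(-6, 6)) {
  if (inherits(equations, "gma_equation")) equations <- list(equations)
  if (!length(equations) || !all(vapply(equations, inherits, TRUE, "gma_equation")))
    stop("equations must be a non-empty list of gma_equation")
  targets <- vapply(equations, `[[`, "", "target")
  if (anyDuplicated(targets))
    stop("each equation must target a distinct dependent variable")
  kinds <- vapply(equations, `[[`, "", "kind")
  dynamic <- targets[kinds == "differential"]
  auxiliary <- targets[kinds == "algebraic"]
  used <- unique(unlist(lapply(equations, function(eq)
    unlist(lapply(c(eq$positive, eq$negative), function(tm) names(tm$vars))))))
  if (length(setdiff(independent, used)))
    warning("independent variable(s) not used in any equation: ",
            paste(setdiff(independent, used), collapse = ", "))
  unknown <- setdiff(used, c(targets, independent))
  if (length(unknown))
    stop("variable(s) used but not defined by an equation nor declared ",
         "independent: ", paste(unknown, collapse = ", "))
  if (length(intersect(independent, targets)))
    stop("independent variables cannot also be equation targets")
  parameters <- sort(unique(unlist(lapply(equations, function(eq)
    unlist(lapply(c(eq$positive, eq$negative), function(tm) names(tm$params)))))))
  bnd <- matrix(rep(as.numeric(default_bounds), length(parameters) + length(independent)),
                nrow = 2, dimnames = list(c("lb", "ub"), c(parameters, independent)))
  if (!is.null(bounds)) {
    if (is.null(colnames(bounds))) stop("bounds must have parameter names as colnames")
    extra <- setdiff(colnames(bounds), colnames(bnd))
    if (length(extra)) stop("bounds given for unknown names: ", paste(extra, collapse = ", "))
    bnd[, colnames(bounds)] <- as.matrix(bounds)
  }
  if (any(bnd["lb", ] > bnd["ub", ])) stop("lower bound exceeds upper bound")
  structure(list(equations = equations, dynamic = unname(dynamic),
                 auxiliary = unname(auxiliary), independent = independent,
                 parameters = parameters, bounds = bnd),
            class = "gma_system")
}

#' Set log10 parameter bounds on a GMA system
#'
#' @param system a [gma_system()].
#' @param ... named length-2 numeric vectors, e.g. `a1 = c(-3, 3)`.
#' @param default optional length-2 numeric applied to every parameter first.
#' @return The system with updated bounds.
#' @export
set_bounds <- function(system, ..., default = NULL) {
  stopifnot(inherits(system, "gma_system"))
  if (!is.null(default)) system$bounds[] <- rep(as.numeric(default), ncol(system$bounds))
  upd <- list(...)
  for (nm in names(upd)) {
    if (!nm %in% colnames(system$bounds)) stop("unknown parameter: ", nm)
    system$bounds[, nm] <- as.numeric(upd[[nm]])
  }
  if (any(system$bounds["lb", ] > system$bounds["ub", ])) stop("lower bound exceeds upper bound")
  system
}

# All dependent variables, in equation (= signature digit) order prefix:
# dynamic first is NOT imposed; order follows the equation list.
dependent_vars <- function(system) vapply(system$equations, `[[`, "", "target")

#' @export
print.gma_system <- function(x, ...) {
  sig <- compute_system_signature(x)
  cat(sprintf("GMA system: %d equations (%d differential, %d algebraic)\n",
              length(x$equations), length(x$dynamic), length(x$auxiliary)))
  cat(sprintf("  signature [%s], %d potential cases\n", sig$flat, total_case_count(sig)))
  cat(sprintf("  parameters (%d): %s\n", length(x$parameters),
              paste(x$parameters, collapse = ", ")))
  if (length(x$independent))
    cat("  independent:", paste(x$independent, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.power_law_term <- function(x, ...) {
  cat(format_term(x), "\n")
  invisible(x)
}

# --- signatures and case numbering ------------------------------------------

#' System signature of a GMA system
#'
#' The signature records, per equation in order, the pair (number of positive
#' terms, number of negative terms).  Its flat form concatenates the digits;
#' the product of all pairs is the number of potential phenotypes.
#'
#' @param system a [gma_system()].
#' @return An object of class `system_signature` with elements `pairs`
#'   (2-column integer matrix) and `flat` (digit string).
#' @examples
#' sys <- relaxation_oscillator()$system
#' compute_system_signature(sys)$flat  # "311121113121"
#' @export
compute_system_signature <- function(system) {
  stopifnot(inherits(system, "gma_system"))
  pairs <- t(vapply(system$equations,
                    function(eq) c(length(eq$positive), length(eq$negative)),
                    integer(2)))
  colnames(pairs) <- c("P", "N")
  structure(list(pairs = pairs, flat = paste(t(pairs), collapse = "")),
            class = "system_signature")
}

#' @export
print.system_signature <- function(x, ...) {
  cat(sprintf("System signature [%s] (%d cases)\n", x$flat, total_case_count(x)))
  invisible(x)
}

#' Number of potential phenotypes of a signature
#'
#' @param signature a `system_signature` (or a [gma_system()]).
#' @return `prod(P_i * N_i)` over all equations.
#' @export
total_case_count <- function(signature) {
  if (inherits(signature, "gma_system")) signature <- compute_system_signature(signature)
  stopifnot(inherits(signature, "system_signature"))
  prod(as.numeric(signature$pairs))
}

# mixed-radix digit order: equation 1 most significant; within an equation the
# positive index is more significant than the negative index (the negative
# index cycles fastest, the convention that reproduces the printed numbering).
case_radices <- function(sys_sig) as.integer(t(sys_sig$pairs))

#' Case number of a case signature
#'
#' Cases are numbered 1..`total_case_count` by conventional digital counting
#' of the case signature digits: the first equation's indices are most
#' significant and, within an equation, the negative-term index cycles faster
#' than the positive-term index.
#'
#' @param sig integer vector of case-signature digits
#'   `(p1, n1, p2, n2, ...)`, or a `case_signature` object.
#' @param sys_sig the `system_signature` bounding `sig`.
#' @return Integer case number.
#' @export
signature_to_number <- function(sig, sys_sig) {
  if (inherits(sig, "case_signature")) sig <- sig$digits
  rad <- case_radices(sys_sig)
  sig <- as.integer(sig)
  if (length(sig) != length(rad)) stop("case signature has wrong length")
  if (any(sig < 1L) || any(sig > rad)) stop("case signature digit out of range")
  place <- rev(cumprod(rev(c(rad[-1], 1L))))
  as.integer(1L + sum((sig - 1L) * place))
}

#' Case signature of a case number
#'
#' Inverse of [signature_to_number()].
#'
#' @param n integer case number in `1..total_case_count(sys_sig)`.
#' @param sys_sig a `system_signature`.
#' @return An object of class `case_signature` with elements `digits`,
#'   `pairs` and `flat`.
#' @export
number_to_signature <- function(n, sys_sig) {
  rad <- case_radices(sys_sig)
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L || n > prod(rad))
    stop("case number out of range 1..", prod(rad))
  x <- n - 1L
  digits <- integer(length(rad))
  for (k in rev(seq_along(rad))) {
    digits[k] <- x %% rad[k]
    x <- x %/% rad[k]
  }
  digits <- digits + 1L
  pairs <- matrix(digits, ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("p", "n")))
  structure(list(digits = digits, pairs = pairs,
                 flat = paste(digits, collapse = "")),
            class = "case_signature")
}

#' @export
print.case_signature <- function(x, ...) {
  cat(sprintf("Case signature (%s)\n", x$flat))
  invisible(x)
}

#' S-system case of a GMA system
#'
#' Bundles a case number with its signature and the selected dominant terms.
#'
#' @param system a [gma_system()].
#' @param n integer case number.
#' @return An object of class `ssystem_case`.
#' @export
ssystem_case <- function(system, n) {
  sys_sig <- compute_system_signature(system)
  sig <- number_to_signature(n, sys_sig)
  structure(list(case_number = as.integer(n), signature = sig,
                 system_signature = sys_sig),
            class = "ssystem_case")
}

#' @export
print.ssystem_case <- function(x, ...) {
  cat(sprintf("Case %d, signature (%s)\n", x$case_number, x$signature$flat))
  invisible(x)
}

#' Extract the dominant S-system of a case
#'
#' Keeps, per equation, only the case's selected positive and negative term.
#' The result is a [gma_system()] whose signature is all (1,1): the tractable
#' subsystem characterizing the phenotype.
#'
#' @param system a [gma_system()].
#' @param case an `ssystem_case`, a case number, or a digit vector.
#' @return A [gma_system()] with one positive and one negative term per
#'   equation and the same variable rosters and bounds.
#' @export
extract_ssystem <- function(system, case) {
  sel <- case_pairs(system, case)
  eqs <- lapply(seq_along(system$equations), function(i) {
    eq <- system$equations[[i]]
    gma_equation(eq$target, eq$positive[sel[i, 1]], eq$negative[sel[i, 2]], eq$kind)
  })
  out <- gma_system(eqs, independent = system$independent)
  # keep the full roster and bounds: parameters absent from the dominant terms
  # remain part of the model
  out$parameters <- system$parameters
  out$bounds <- system$bounds
  out
}

# normalize a case specification to a (neq x 2) matrix of selected indices
case_pairs <- function(system, case) {
  sys_sig <- compute_system_signature(system)
  if (inherits(case, "ssystem_case")) return(case$signature$pairs)
  if (inherits(case, "case_signature")) return(case$pairs)
  if (length(case) == 1L) return(number_to_signature(case, sys_sig)$pairs)
  rad <- case_radices(sys_sig)
  if (length(case) != length(rad)) stop("case digit vector has wrong length")
  signature_to_number(case, sys_sig)  # bounds check
  matrix(as.integer(case), ncol = 2, byrow = TRUE)
}

# --- numeric evaluation ------------------------------------------------------

# log10 of a term at a named state/parameter assignment
eval_term_log10 <- function(tm, values) {
  v <- log10(tm$const)
  if (length(tm$params)) v <- v + sum(tm$params * log10(values[names(tm$params)]))
  if (length(tm$vars)) v <- v + sum(tm$vars * log10(values[names(tm$vars)]))
  unname(v)
}

eval_term <- function(tm, values) 10^eval_term_log10(tm, values)

# right-hand sides of all equations at a named assignment of every variable
# and parameter (auxiliary variables must be included in `values`)
eval_rhs <- function(system, values) {
  vapply(system$equations, function(eq) {
    sum(vapply(eq$positive, eval_term, 0, values = values)) -
      sum(vapply(eq$negative, eval_term, 0, values = values))
  }, 0)
}

# solve auxiliary variables from their defining sums (algebraic equations,
# which by convention have the auxiliary as the single negative term).
# Works when auxiliary dependencies are acyclic.
solve_auxiliaries <- function(system, values, max_pass = NULL) {
  aux <- system$auxiliary
  if (!length(aux)) return(values)
  remaining <- aux
  if (is.null(max_pass)) max_pass <- length(aux) + 1L
  eq_of <- structure(system$equations[match(aux, dependent_vars(system))], names = aux)
  for (pass in seq_len(max_pass)) {
    progressed <- FALSE
    for (a in remaining) {
      eq <- eq_of[[a]]
      needs <- unique(unlist(lapply(eq$positive, function(tm) names(tm$vars))))
      if (all(!needs %in% remaining)) {
        values[a] <- sum(vapply(eq$positive, eval_term, 0, values = values))
        remaining <- setdiff(remaining, a)
        progressed <- TRUE
      }
    }
    if (!length(remaining)) return(values)
    if (!progressed) stop("cyclic auxiliary-variable dependencies; cannot substitute")
  }
  values
}
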