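#' Ratio block of a rational rate law
#'
#' One signed contribution to a rate: a sum of power-law terms divided by a
#' sum of power-law terms (denominator may be the constant 1).
#'
#' @param sign `+1` (production) or `-1` (consumption).
#' @param num non-empty list of [power_law_term()]s (the numerator sum).
#' @param den list of [power_law_term()]s (the denominator sum); `NULL`
#'   means 1.
#' @return An object of class `ratio_block`.
#' @export
ratio_block <- function(sign, num, den = NULL) {
  stopifnot(sign %in% c(-1, 1))
  if (inherits(num, "power_law_term")) num <- list(num)
  if (inherits(den, "power_law_term")) den <- list(den)
  if (is.null(den)) den <- list(power_law_term(1))
  stopifnot(length(num) >= 1, all(vapply(num, inherits, TRUE, "power_law_term")),
            all(vapply(den, inherits, TRUE, "power_law_term")))
  structure(list(sign = sign, num = num, den = den), class = "ratio_block")
}

#' Rational-rate ODE model
#'
#' An ODE system whose right-hand sides are signed sums of [ratio_block()]s:
#' every rate is a ratio of sums of power-law terms.  Such models (e.g.
#' saturable binding kinetics) can be recast exactly into GMA form with
#' [recast_to_gma()].
#'
#' @param equations named list: one list of [ratio_block()]s per dynamic
#'   variable (names are the variable names).
#' @param independent character vector of independent variable names.
#' @return An object of class `rational_model`.
#' @export
rational_model <- function(equations, independent = character(0)) {
  stopifnot(is.list(equations), length(equations) >= 1,
            !is.null(names(equations)), all(nzchar(names(equations))))
  for (blocks in equations) {
    if (inherits(blocks, "ratio_block")) next
    stopifnot(is.list(blocks), all(vapply(blocks, inherits, TRUE, "ratio_block")))
  }
  equations <- lapply(equations, function(b) if (inherits(b, "ratio_block")) list(b) else b)
  structure(list(equations = equations, independent = independent),
            class = "rational_model")
}

#' @export
print.rational_model <- function(x, ...) {
  cat(sprintf("Rational ODE model: %d equation(s) (%s)\n",
              length(x$equations), paste(names(x$equations), collapse = ", ")))
  invisible(x)
}

# canonical fingerprint of a term list, for matching identical denominators
canonical_terms <- function(terms) {
  srt <- function(x) if (length(x)) x[order(names(x))] else x
  fmt <- function(x) if (length(x)) paste(names(x), format(x, digits = 15),
                                          collapse = ",") else ""
  paste(sort(vapply(terms, function(tm)
    paste(format(tm$const, digits = 15), fmt(srt(tm$params)), fmt(srt(tm$vars)),
          sep = "|"), "")), collapse = ";")
}

# divide a term by a single-term denominator
fold_term <- function(tm, den) {
  params <- tm$params
  for (nm in names(den$params)) params[nm] <- (params[nm] %||0% 0) - den$params[[nm]]
  vars <- tm$vars
  for (nm in names(den$vars)) vars[nm] <- (vars[nm] %||0% 0) - den$vars[[nm]]
  power_law_term(tm$const / den$const, params, vars)
}
`%||0%` <- function(a, b) if (length(a) == 1 && !is.na(a)) a else b

# multiply a term by aux^-1
times_inv_aux <- function(tm, aux) {
  vars <- tm$vars
  vars[aux] <- (vars[aux] %||0% 0) - 1
  power_law_term(tm$const, tm$params, vars)
}

#' Recast a rational model into GMA form
#'
#' Every distinct denominator with two or more terms is assigned one
#' auxiliary variable `d` and one algebraic equation `0 = (denominator
#' terms) - d`; the ratio is replaced by the numerator terms times
#' `d^-1`.  Single-term denominators are folded into the numerator
#' directly.  Auxiliary equations are appended after all differential
#' equations in order of first appearance.  The recast system has exactly
#' the same right-hand-side values as the original model.
#'
#' @param model a [rational_model()].
#' @param aux_names optional character vector of names for the auxiliary
#'   variables, in order of first appearance (default `d1`, `d2`, ...).
#' @param bounds,default_bounds passed to [gma_system()].
#' @return A [gma_system()].
#' @export
recast_to_gma <- function(model, aux_names = NULL, bounds = NULL,
                          default_bounds = c(-6, 6)) {
  stopifnot(inherits(model, "rational_model"))
  den_keys <- character(0)   # canonical key -> aux name
  den_terms <- list()
  aux_of <- function(terms) {
    key <- canonical_terms(terms)
    hit <- match(key, den_keys)
    if (!is.na(hit)) return(names(den_keys)[hit])
    nm <- if (!is.null(aux_names) && length(den_keys) < length(aux_names))
      aux_names[length(den_keys) + 1L] else paste0("d", length(den_keys) + 1L)
    den_keys <<- c(den_keys, stats::setNames(key, nm))
    names(den_keys)[length(den_keys)] <<- nm
    den_terms[[nm]] <<- terms
    nm
  }
  eqs <- list()
  for (tgt in names(model$equations)) {
    pos <- list(); neg <- list()
    for (blk in model$equations[[tgt]]) {
      if (length(blk$den) == 1L) {
        terms <- lapply(blk$num, fold_term, den = blk$den[[1]])
      } else {
        aux <- aux_of(blk$den)
        terms <- lapply(blk$num, times_inv_aux, aux = aux)
      }
      if (blk$sign > 0) pos <- c(pos, terms) else neg <- c(neg, terms)
    }
    eqs[[length(eqs) + 1L]] <- gma_equation(tgt, pos, neg, "differential")
  }
  for (nm in names(den_terms)) {
    eqs[[length(eqs) + 1L]] <- gma_equation(
      nm, den_terms[[nm]], list(power_law_term(1, vars = stats::setNames(1, nm))),
      "algebraic")
  }
  gma_system(eqs, independent = model$independent, bounds = bounds,
             default_bounds = default_bounds)
}

# numeric right-hand sides of a rational model at a named assignment
eval_rational_rhs <- function(model, values) {
  vapply(names(model$equations), function(tgt) {
    s <- 0
    for (blk in model$equations[[tgt]]) {
      num <- sum(vapply(blk$num, eval_term, 0, values = values))
      den <- sum(vapply(blk$den, eval_term, 0, values = values))
      s <- s + blk$sign * num / den
    }
    s
  }, 0)
}
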