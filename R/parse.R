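# Plain-text model grammar, one equation per line:
#   X1' = a1*d1^-1 + a1*rA1*(X2/KA1)^2*d1^-1 - g1*X1     (differential)
#   0 = 1 + (X2/KA1)^2 + (X4/KR1)^2 - d1                 (algebraic)
# optional header lines:
#   independent: S1 S2
#   bounds: a1 -3 3
# '#' starts a comment; '*' multiplies factors; '^' takes a (possibly
# negative, possibly fractional) exponent; (A/B)^n expands to A^n * B^-n.
# Identifiers that are equation targets (or declared independent) are
# variables; all remaining identifiers are parameters.

#' Parse a GMA model from its text format
#'
#' @param text a single string (possibly multi-line), a character vector of
#'   lines, or a file path ending in `.txt`/`.gma` to read.
#' @return A [gma_system()].
#' @examples
#' parse_model_file("X1' = a - b*X1")
#' @seealso [write_model_file()] for the inverse.
#' @export
parse_model_file <- function(text) {
  if (length(text) == 1L && grepl("\\.(txt|gma)$", text) && file.exists(text))
    text <- readLines(text)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  independent <- character(0)
  bound_rows <- list()
  raw <- list()
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (!nzchar(s)) next
    if (grepl("^independent\\s*:", s)) {
      independent <- c(independent,
                       strsplit(trimws(sub("^independent\\s*:", "", s)), "\\s+")[[1]])
      next
    }
    if (grepl("^bounds\\s*:", s)) {
      f <- strsplit(trimws(sub("^bounds\\s*:", "", s)), "[[:space:],]+")[[1]]
      f <- f[nzchar(f)]
      if (length(f) != 3L) stop("line ", ln, ": bounds line must be 'bounds: name lo hi'")
      bound_rows[[f[1]]] <- as.numeric(f[2:3])
      next
    }
    eqp <- strsplit(s, "=", fixed = TRUE)[[1]]
    if (length(eqp) != 2L) stop("line ", ln, ": expected exactly one '='")
    lhs <- trimws(eqp[1]); rhs <- trimws(eqp[2])
    kind <- if (lhs == "0") "algebraic"
    else if (grepl("^[A-Za-z][A-Za-z0-9_.]*'$", lhs)) "differential"
    else stop("line ", ln, ": left side must be 0 or a variable followed by '")
    target <- if (kind == "differential") sub("'$", "", lhs) else NA_character_
    terms <- split_signed_terms(rhs, ln)
    raw[[length(raw) + 1L]] <- list(line = ln, kind = kind, target = target,
                                    terms = terms)
  }
  if (!length(raw)) stop("no equations found")
  parsed <- lapply(raw, function(r) {
    r$terms <- lapply(r$terms, function(tt)
      c(tt["sign"], list(factors = parse_term_factors(tt$text[[1]], r$line))))
    r
  })
  # resolve algebraic targets: the single negative bare-variable term
  for (i in seq_along(parsed)) {
    r <- parsed[[i]]
    if (r$kind != "algebraic") next
    negs <- Filter(function(tt) tt$sign < 0, r$terms)
    if (length(negs) != 1L)
      stop("line ", r$line, ": algebraic equation must have exactly one negative term")
    f <- negs[[1]]$factors
    if (f$const != 1 || length(f$expo) != 1L || f$expo != 1)
      stop("line ", r$line, ": the negative term of an algebraic equation must ",
           "be the bare auxiliary variable")
    parsed[[i]]$target <- names(f$expo)
  }
  targets <- vapply(parsed, `[[`, "", "target")
  if (anyDuplicated(targets)) stop("duplicate equation target(s)")
  varnames <- c(targets, independent)
  eqs <- lapply(parsed, function(r) {
    mk <- function(f) {
      isvar <- names(f$expo) %in% varnames
      power_law_term(const = f$const,
                     params = f$expo[!isvar], vars = f$expo[isvar])
    }
    pos <- lapply(Filter(function(tt) tt$sign > 0, r$terms), function(tt) mk(tt$factors))
    neg <- lapply(Filter(function(tt) tt$sign < 0, r$terms), function(tt) mk(tt$factors))
    if (!length(pos) || !length(neg))
      stop("line ", r$line, ": every equation needs at least one positive and ",
           "one negative term")
    gma_equation(r$target, pos, neg, r$kind)
  })
  bounds <- NULL
  if (length(bound_rows)) {
    bounds <- matrix(unlist(bound_rows), nrow = 2,
                     dimnames = list(c("lb", "ub"), names(bound_rows)))
  }
  gma_system(eqs, independent = independent, bounds = bounds)
}

# split "a + b - c" into signed term texts, ignoring signs inside exponents
split_signed_terms <- function(s, line) {
  chars <- strsplit(s, "")[[1]]
  terms <- list(); cur <- ""; sign <- 1
  prev_nonspace <- ""
  for (ch in chars) {
    if (ch %in% c("+", "-") && !prev_nonspace %in% c("^", "(", "e", "E", "*", "/", "")) {
      if (!nzchar(trimws(cur))) stop("line ", line, ": empty term")
      terms[[length(terms) + 1L]] <- list(sign = sign, text = trimws(cur))
      cur <- ""; sign <- if (ch == "-") -1 else 1
    } else {
      cur <- paste0(cur, ch)
    }
    if (ch != " ") prev_nonspace <- ch
  }
  if (!nzchar(trimws(cur))) stop("line ", line, ": empty term")
  terms[[length(terms) + 1L]] <- list(sign = sign, text = trimws(cur))
  terms
}

# parse one term "2*a1*(X2/KA1)^2*d1^-1" -> list(const, expo = named exponents)
parse_term_factors <- function(txt, line) {
  num_re <- "[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?"
  id_re <- "[A-Za-z][A-Za-z0-9_.]*"
  exp_re <- sprintf("(-?%s|-?[0-9]+/[0-9]+|\\(-?[0-9]+(/[0-9]+)?\\))", num_re)
  fac_res <- c(
    ratio = sprintf("^\\((%s)/(%s)\\)(\\^%s)?", id_re, id_re, exp_re),
    ident = sprintf("^(%s)(\\^%s)?", id_re, exp_re),
    num = sprintf("^(%s)", num_re))
  parse_exp <- function(e) {
    if (is.na(e) || !nzchar(e)) return(1)
    e <- sub("^\\^", "", e)
    e <- gsub("[()]", "", e)
    if (grepl("/", e, fixed = TRUE)) {
      pq <- as.numeric(strsplit(e, "/", fixed = TRUE)[[1]])
      return(pq[1] / pq[2])
    }
    as.numeric(e)
  }
  const <- 1; expo <- numeric(0)
  add <- function(nm, e) {
    expo[nm] <<- (if (nm %in% names(expo)) expo[[nm]] else 0) + e
  }
  rest <- gsub("\\s+", "", txt)
  first <- TRUE
  while (nzchar(rest)) {
    if (!first) {
      if (!startsWith(rest, "*"))
        stop("line ", line, ": expected '*' near '", substr(rest, 1, 12), "'")
      rest <- substr(rest, 2, nchar(rest))
    }
    first <- FALSE
    m <- regexpr(fac_res["ratio"], rest, perl = TRUE)
    if (m == 1L) {
      tok <- regmatches(rest, m)
      inner <- sub("^\\(", "", sub(")\\^.*$|\\)$", "", tok))
      pq <- strsplit(inner, "/", fixed = TRUE)[[1]]
      e <- parse_exp(sub("^[^^]*", "", tok))
      add(pq[1], e); add(pq[2], -e)
      rest <- substr(rest, attr(m, "match.length") + 1L, nchar(rest))
      next
    }
    m <- regexpr(fac_res["ident"], rest, perl = TRUE)
    if (m == 1L) {
      tok <- regmatches(rest, m)
      nm <- sub("\\^.*$", "", tok)
      e <- parse_exp(sub("^[^^]*", "", tok))
      add(nm, e)
      rest <- substr(rest, attr(m, "match.length") + 1L, nchar(rest))
      if (startsWith(rest, "^"))
        stop("line ", line, ": malformed exponent near '", substr(rest, 1, 8), "'")
      next
    }
    m <- regexpr(fac_res["num"], rest, perl = TRUE)
    if (m == 1L) {
      tok <- regmatches(rest, m)
      v <- as.numeric(tok)
      if (!is.finite(v) || v <= 0)
        stop("line ", line, ": non-positive numeric constant '", tok, "'")
      const <- const * v
      rest <- substr(rest, attr(m, "match.length") + 1L, nchar(rest))
      next
    }
    stop("line ", line, ": cannot parse factor near '", substr(rest, 1, 12), "'")
  }
  list(const = const, expo = expo[expo != 0])
}

format_term <- function(tm) {
  parts <- character(0)
  if (tm$const != 1 || (!length(tm$params) && !length(tm$vars)))
    parts <- format(tm$const, digits = 15)
  fmt1 <- function(nm, e) {
    if (e == 1) nm
    else if (e == round(e)) sprintf("%s^%d", nm, as.integer(e))
    else sprintf("%s^%s", nm, format(e, digits = 15))
  }
  for (nm in names(tm$params)) parts <- c(parts, fmt1(nm, tm$params[[nm]]))
  for (nm in names(tm$vars)) parts <- c(parts, fmt1(nm, tm$vars[[nm]]))
  paste(parts, collapse = "*")
}

#' Serialize a GMA system to the model text format
#'
#' Writes the header (independent variables and per-parameter log10 bounds)
#' followed by one equation per line.  `parse_model_file()` of the output
#' reconstructs an identical system.
#'
#' @param system a [gma_system()].
#' @param path optional file path; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`), the character
#'   vector of lines.
#' @export
write_model_file <- function(system, path = NULL) {
  stopifnot(inherits(system, "gma_system"))
  out <- character(0)
  if (length(system$independent))
    out <- c(out, paste("independent:", paste(system$independent, collapse = " ")))
  for (nm in colnames(system$bounds))
    out <- c(out, sprintf("bounds: %s %s %s", nm,
                          format(system$bounds["lb", nm], digits = 15),
                          format(system$bounds["ub", nm], digits = 15)))
  for (eq in system$equations) {
    lhs <- if (eq$kind == "differential") paste0(eq$target, "'") else "0"
    rhs <- paste(vapply(eq$positive, format_term, ""), collapse = " + ")
    rhs <- paste(rhs, paste(vapply(eq$negative, format_term, ""), collapse = " - "),
                 sep = " - ")
    out <- c(out, paste(lhs, "=", rhs))
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
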