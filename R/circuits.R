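# The two-gene activator-repressor circuit family.
#
# Species: X1 activator mRNA, X2 mature activator protein, X3 repressor
# mRNA, X4 mature repressor protein; d1, d3 are the promoter binding
# polynomials of genes 1 and 3 (auxiliary variables after recasting).
# Nascent proteins are lumped into the effective translation rate constants
# k2, k4, and degradation plus dilution into the lumped inactivation rates
# g1..g4, so each gene contributes one mRNA and one protein equation.
#
# Transcription control modes per gene (binary indices pi, delta):
#   dual (delta = 1): both regulators bind the promoter, mutually
#     exclusively; only the PRIMARY regulator (pi = 1 activator, pi = 0
#     repressor) changes the transcription rate, with fold-change rho; the
#     other regulator antagonizes it by competitive occupancy.
#       pi = 1:  rate = a * (1 + rA*A + R) / (1 + A + R),  rA >= 1
#       pi = 0:  rate = a * (1 + A + rR*R) / (1 + A + R),  rR <= 1
#   single (delta = 0): one regulator only -- the repressor for gene 1
#     (pi1 = 0), the activator for gene 3 (pi3 = 1):
#       gene 1: a * (1 + rR*R) / (1 + R);  gene 3: a * (1 + rA*A) / (1 + A)
#   constitutive: the single-mode site is retained with its fold pinned to
#     1 (neutral binding), i.e. gene 1 with pi1 = 1, gene 3 with pi3 = 0.
# Occupancy functions: A_i = (X2/KA_i)^nA, R_i = (X4/KR_i)^nR.

#' Catalog of the 16 two-gene circuit designs
#'
#' @return Data frame with columns `id` (D.1 to D.16) and the binary mode
#'   indices `pi1`, `delta1`, `pi3`, `delta3`.
#' @export
design_catalog <- function() {
  data.frame(
    id = paste0("D.", 1:16),
    pi1    = c(0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 1),
    delta1 = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1),
    pi3    = c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1),
    delta3 = c(0, 0, 1, 1, 0, 0, 1, 1, 0, 0, 1, 1, 0, 0, 1, 1),
    stringsAsFactors = FALSE)
}

# gene mode from its indices: "dual", "single" or "constitutive"
gene_mode <- function(gene, pi, delta) {
  if (delta == 1) return("dual")
  if (gene == 1) { if (pi == 0) "single" else "constitutive" }
  else { if (pi == 1) "single" else "constitutive" }
}

# promoter numerator/denominator term lists for one gene; n_A, n_R are the
# effective cooperativities of activator/repressor binding at THIS promoter
promoter_terms <- function(gene, mode, pi, n_A, n_R) {
  X_A <- "X2"; X_R <- "X4"
  KA <- paste0("KA", gene); KR <- paste0("KR", gene)
  a <- paste0("a", gene)
  rA <- paste0("rA", gene); rR <- paste0("rR", gene)
  term <- function(params, vars = NULL) power_law_term(params = params, vars = vars %||% numeric(0))
  basal <- term(stats::setNames(1, a))
  act <- function(fold) {
    p <- stats::setNames(c(1, -n_A), c(a, KA))
    if (fold) p <- c(p, stats::setNames(1, rA))
    term(p, stats::setNames(n_A, X_A))
  }
  rep_ <- function(fold) {
    p <- stats::setNames(c(1, -n_R), c(a, KR))
    if (fold) p <- c(p, stats::setNames(1, rR))
    term(p, stats::setNames(n_R, X_R))
  }
  dA <- term(stats::setNames(-n_A, KA), stats::setNames(n_A, X_A))
  dR <- term(stats::setNames(-n_R, KR), stats::setNames(n_R, X_R))
  one <- power_law_term(1)
  if (mode == "dual") {
    num <- if (pi == 1) list(basal, act(TRUE), rep_(FALSE))
           else list(basal, act(FALSE), rep_(TRUE))
    den <- list(one, dA, dR)
  } else if (mode == "single") {
    if (gene == 1) { num <- list(basal, rep_(TRUE)); den <- list(one, dR) }
    else { num <- list(basal, act(TRUE)); den <- list(one, dA) }
  } else {  # constitutive: neutral site, fold pinned to 1
    if (gene == 1) { num <- list(basal, rep_(FALSE)); den <- list(one, dR) }
    else { num <- list(basal, act(FALSE)); den <- list(one, dA) }
  }
  list(num = num, den = den)
}

#' Build one circuit of the two-gene family
#'
#' Constructs the rational-rate model for the design given by the binary
#' mode indices and recasts it into GMA form (equations ordered X1, X2, X3,
#' X4, d1, d3).  Fold-change bounds encode the mode constraints: activator
#' folds `rA*` have log10 bounds \[0, 6\] (activation), repressor folds
#' `rR*` \[-6, 0\] (repression); all other parameters \[-6, 6\].
#'
#' @param pi1,delta1,pi3,delta3 binary mode indices; alternatively pass a
#'   design identifier `"D.1"`..`"D.16"` as `pi1`.
#' @param n_A effective cooperativities of activator binding at gene 1 and
#'   gene 3 (length 2, recycled; defaults `c(2, 4)`: the autogenous
#'   activator promoter responds with effective order 2, the repressor-gene
#'   promoter, driven by tandem cooperative activator sites, with 4).
#' @param n_R effective cooperativities of repressor binding at the two
#'   promoters (length 2, recycled; default 2).
#' @return An object of class `circuit_model`: list with `id`, `indices`,
#'   `system` (the recast [gma_system()]), `rational` (the
#'   [rational_model()]), `n_A`, `n_R`.
#' @examples
#' circ <- build_circuit(1, 1, 1, 0)  # the relaxation oscillator design
#' compute_system_signature(circ$system)$flat
#' @export
build_circuit <- function(pi1, delta1 = NULL, pi3 = NULL, delta3 = NULL,
                          n_A = c(2, 4), n_R = c(2, 2)) {
  cat_ <- design_catalog()
  if (is.character(pi1)) {
    row <- cat_[cat_$id == pi1, ]
    if (!nrow(row)) stop("unknown design identifier: ", pi1)
    delta1 <- row$delta1; pi3 <- row$pi3; delta3 <- row$delta3; pi1 <- row$pi1
  }
  stopifnot(pi1 %in% 0:1, delta1 %in% 0:1, pi3 %in% 0:1, delta3 %in% 0:1)
  n_A <- rep_len(n_A, 2L); n_R <- rep_len(n_R, 2L)
  mode1 <- gene_mode(1, pi1, delta1)
  mode3 <- gene_mode(3, pi3, delta3)
  p1 <- promoter_terms(1, mode1, pi1, n_A[1], n_R[1])
  p3 <- promoter_terms(3, mode3, pi3, n_A[2], n_R[2])
  lin <- function(k, x) power_law_term(params = stats::setNames(1, k),
                                       vars = stats::setNames(1, x))
  eqs <- list(
    X1 = list(ratio_block(+1, p1$num, p1$den),
              ratio_block(-1, lin("g1", "X1"))),
    X2 = list(ratio_block(+1, lin("k2", "X1")),
              ratio_block(-1, lin("g2", "X2"))),
    X3 = list(ratio_block(+1, p3$num, p3$den),
              ratio_block(-1, lin("g3", "X3"))),
    X4 = list(ratio_block(+1, lin("k4", "X3")),
              ratio_block(-1, lin("g4", "X4"))))
  model <- rational_model(eqs)
  system <- recast_to_gma(model, aux_names = c("d1", "d3"))
  fold_bounds <- list()
  for (nm in system$parameters) {
    if (grepl("^rA", nm)) fold_bounds[[nm]] <- c(0, 6)
    if (grepl("^rR", nm)) fold_bounds[[nm]] <- c(-6, 0)
  }
  if (length(fold_bounds))
    system <- do.call(set_bounds, c(list(system), fold_bounds))
  idx <- c(pi1 = pi1, delta1 = delta1, pi3 = pi3, delta3 = delta3)
  id <- cat_$id[cat_$pi1 == pi1 & cat_$delta1 == delta1 &
                  cat_$pi3 == pi3 & cat_$delta3 == delta3]
  structure(list(id = id, indices = idx, modes = c(gene1 = mode1, gene3 = mode3),
                 system = system, rational = model, n_A = n_A, n_R = n_R),
            class = "circuit_model")
}

#' @export
print.circuit_model <- function(x, ...) {
  cat(sprintf("Two-gene circuit %s (pi1=%d, delta1=%d, pi3=%d, delta3=%d): gene1 %s, gene3 %s\n",
              x$id, x$indices[1], x$indices[2], x$indices[3], x$indices[4],
              x$modes[1], x$modes[2]))
  cat(sprintf("  signature [%s], cooperativities n_A=(%s), n_R=(%s)\n",
              compute_system_signature(x$system)$flat,
              paste(x$n_A, collapse = ","), paste(x$n_R, collapse = ",")))
  invisible(x)
}

#' The two-gene relaxation oscillator design
#'
#' Dual control of the activator gene (activator-primary) and single
#' activator control of the repressor gene: indices (1, 1, 1, 0), design
#' D.14.
#'
#' @inheritParams build_circuit
#' @return A `circuit_model`.
#' @export
relaxation_oscillator <- function(n_A = c(2, 4), n_R = c(2, 2))
  build_circuit(1, 1, 1, 0, n_A = n_A, n_R = n_R)

#' Screen the 16 circuit designs
#'
#' For every design: enumerate the phenotypic repertoire and classify the
#' dynamics of each valid phenotype, reporting the number (and case
#' numbers) of phenotypes with oscillatory potential.
#'
#' @param designs character vector of design ids (default all 16).
#' @param bounds optional log10 bounds override.
#' @param probe_budget,seed passed to [classify_case_dynamics()].
#' @param n_A,n_R cooperativities.
#' @param verbose print one line per design.
#' @return An object of class `design_screen`: data frame `table` (design,
#'   indices, valid, total, n_oscillatory, oscillatory_cases) plus
#'   per-design details.
#' @export
screen_designs <- function(designs = design_catalog()$id, bounds = NULL,
                           probe_budget = 200L, seed = 1L, n_A = c(2, 4),
                           n_R = c(2, 2), verbose = FALSE) {
  cat_ <- design_catalog()
  rows <- list(); details <- list()
  for (id in designs) {
    circ <- build_circuit(id, n_A = n_A, n_R = n_R)
    rep_ <- enumerate_repertoire(circ$system, bounds = bounds)
    osc <- integer(0)
    dyn <- list()
    for (n in rep_$valid_cases) {
      cd <- classify_case_dynamics(circ$system, n, bounds = bounds,
                                   probe_budget = probe_budget,
                                   seed = seed + n)
      dyn[[as.character(n)]] <- cd
      if (cd$oscillatory_potential) osc <- c(osc, n)
    }
    i <- match(id, cat_$id)
    rows[[id]] <- data.frame(
      design = id, pi1 = cat_$pi1[i], delta1 = cat_$delta1[i],
      pi3 = cat_$pi3[i], delta3 = cat_$delta3[i],
      valid = length(rep_$valid_cases), total = nrow(rep_$table),
      n_oscillatory = length(osc),
      oscillatory_cases = paste(osc, collapse = ";"),
      stringsAsFactors = FALSE)
    details[[id]] <- list(circuit = circ, repertoire = rep_, dynamics = dyn)
    if (verbose)
      message(sprintf("%s: %d/%d valid, %d oscillatory (%s)", id,
                      length(rep_$valid_cases), nrow(rep_$table), length(osc),
                      paste(osc, collapse = ", ")))
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 details = details, seed = seed),
            class = "design_screen")
}

#' @export
print.design_screen <- function(x, ...) {
  cat("Design screen:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a design screen to CSV
#'
#' @param screen a `design_screen`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_screen_csv <- function(screen, path) {
  utils::write.csv(screen$table, path, row.names = FALSE)
  invisible(path)
}
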