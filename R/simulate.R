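#' Simulate the full (pre-dominance) model
#'
#' Integrates the full nonlinear system -- either a [rational_model()] or a
#' [gma_system()] whose auxiliary variables are substituted algebraically by
#' their defining sums -- with a stiff-capable solver
#' ([deSolve::lsoda()]).  Time is in hours.  When no initial state is given,
#' the default is the S-system fixed point of `case` perturbed by +10% in
#' every dynamic variable.
#'
#' @param model a [gma_system()] or [rational_model()].
#' @param params named, strictly positive parameter vector (including any
#'   independent variables).
#' @param t_end end time in hours (default 100).
#' @param initial_state named vector of dynamic-variable start values; when
#'   `NULL`, derived from `case`.
#' @param case case used for the default initial state (required if
#'   `initial_state` is `NULL` and `model` is a [gma_system()]; for a
#'   rational model a recast system must be supplied via `gma`).
#' @param gma optional [gma_system()] matching a rational `model`, used only
#'   to build the default initial state.
#' @param perturb relative perturbation of the default initial state.
#' @param n_out number of equally spaced output times.
#' @param rtol,atol integration tolerances.
#' @return An object of class `trajectory`: `time`, `states` (matrix, one
#'   column per dynamic variable), `params`.
#' @export
simulate_full_system <- function(model, params, t_end = 100,
                                 initial_state = NULL, case = NULL,
                                 gma = NULL, perturb = 0.1, n_out = 2000L,
                                 rtol = 1e-8, atol = 1e-10) {
  if (any(params <= 0)) stop("parameters must be strictly positive")
  if (inherits(model, "rational_model")) {
    vars <- names(model$equations)
    rhs_fun <- function(x) eval_rational_rhs(model, c(x, params))
  } else if (inherits(model, "gma_system")) {
    vars <- model$dynamic
    dyn_idx <- match(vars, dependent_vars(model))
    rhs_fun <- function(x) {
      values <- solve_auxiliaries(model, c(x, params))
      eval_rhs(model, values)[dyn_idx]
    }
  } else stop("model must be a gma_system or rational_model")
  if (is.null(initial_state)) {
    src <- if (inherits(model, "gma_system")) model else gma
    if (is.null(case) || is.null(src))
      stop("either initial_state, or case (and for rational models a recast ",
           "gma system), must be given")
    fp <- fixed_point(src, case, params)
    initial_state <- fp$concentrations[src$dynamic] * (1 + perturb)
    names(initial_state) <- src$dynamic
  }
  initial_state <- initial_state[vars]
  if (any(is.na(initial_state)) || any(initial_state <= 0))
    stop("initial state must be strictly positive for all dynamic variables")
  times <- seq(0, t_end, length.out = n_out)
  deriv <- function(t, y, parms) {
    y <- pmax(y, 1e-300)
    names(y) <- vars
    list(rhs_fun(y))
  }
  sol <- deSolve::lsoda(y = initial_state, times = times, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) stop("integration failed (lsoda istate < 0)")
  states <- as.matrix(sol[, -1, drop = FALSE])
  colnames(states) <- vars
  structure(list(time = sol[, 1], states = states, params = params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d time points over [0, %g] h, variables: %s\n",
              length(x$time), max(x$time), paste(colnames(x$states), collapse = ", ")))
  invisible(x)
}

#' Classify a simulated trajectory
#'
#' Inspects one variable (by default the last dynamic variable, the mature
#' repressor in the circuit family) over the final `window` fraction of the
#' time span.  With fewer than `min_extrema` local extrema the trajectory is
#' `monotone_or_none`.  Otherwise the ratio of the last to the first
#' peak-to-trough amplitude decides: within `band` the oscillation is
#' sustained; below it, with at least three detected cycles, damped;
#' anything else (including still-growing transients) is `monotone_or_none`.
#'
#' @param traj a `trajectory`.
#' @param var variable name to analyze.
#' @param window final fraction of the time span analyzed.
#' @param band sustained-amplitude ratio band.
#' @param min_extrema minimum number of extrema for an oscillation call.
#' @return One of `"sustained_oscillation"`, `"damped_oscillation"`,
#'   `"monotone_or_none"`.
#' @export
classify_trajectory <- function(traj, var = NULL, window = 0.5,
                                band = c(0.95, 1.05), min_extrema = 6L) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(var)) var <- colnames(traj$states)[ncol(traj$states)]
  s <- traj$states[, var]
  t <- traj$time
  keep <- t >= max(t) - window * (max(t) - min(t))
  s <- s[keep]
  rng <- diff(range(s))
  if (!is.finite(rng) || rng <= 1e-12 * max(abs(s), 1e-300))
    return("monotone_or_none")
  ext <- find_extrema(s)
  if (nrow(ext) < min_extrema) return("monotone_or_none")
  # successive peak-to-trough amplitudes
  amps <- numeric(0)
  for (i in seq_len(nrow(ext) - 1L)) {
    if (ext$type[i] == "max" && ext$type[i + 1L] == "min")
      amps <- c(amps, ext$value[i] - ext$value[i + 1L])
  }
  if (length(amps) < 2L) return("monotone_or_none")
  ratio <- amps[length(amps)] / amps[1]
  if (ratio >= band[1] && ratio <= band[2]) return("sustained_oscillation")
  if (ratio < band[1] && length(amps) >= 3L) return("damped_oscillation")
  "monotone_or_none"
}

# strict local extrema of a series, with a small prominence filter relative
# to the series range
find_extrema <- function(s, prom = 1e-6) {
  rng <- diff(range(s))
  n <- length(s)
  idx <- integer(0); type <- character(0)
  for (i in 2:(n - 1L)) {
    if (s[i] > s[i - 1L] && s[i] >= s[i + 1L]) { idx <- c(idx, i); type <- c(type, "max") }
    else if (s[i] < s[i - 1L] && s[i] <= s[i + 1L]) { idx <- c(idx, i); type <- c(type, "min") }
  }
  keep <- rep(TRUE, length(idx))
  if (length(idx) > 1L) {
    for (i in seq_len(length(idx) - 1L))
      if (abs(s[idx[i + 1L]] - s[idx[i]]) < prom * rng) keep[c(i, i + 1L)] <- FALSE
  }
  data.frame(index = idx[keep], type = type[keep], value = s[idx[keep]],
             stringsAsFactors = FALSE)
}

#' Write a trajectory to CSV
#'
#' @param traj a `trajectory`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time = traj$time, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
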