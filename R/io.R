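#' Analysis configuration defaults
#'
#' Central collection of tunable numerical settings, recorded in every
#' serialized output.
#'
#' @param default_bounds default log10 parameter bounds.
#' @param eps_slack strict-slack validity threshold (log10 units).
#' @param probe_budget hit-and-run probes per case for dynamics probing.
#' @param seed integer seed for all randomized steps.
#' @param resolution slice grid resolution.
#' @param sustained_band amplitude-ratio band for sustained oscillation.
#' @param t_end default simulation horizon (hours).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(default_bounds = c(-6, 6), eps_slack = 1e-6,
                            probe_budget = 200L, seed = 1L,
                            resolution = 301L, sustained_band = c(0.95, 1.05),
                            t_end = 100) {
  structure(list(default_bounds = default_bounds, eps_slack = eps_slack,
                 probe_budget = as.integer(probe_budget),
                 seed = as.integer(seed), resolution = as.integer(resolution),
                 sustained_band = sustained_band, t_end = t_end,
                 package_version = as.character(utils::packageVersion("designspacer"))),
            class = "analysis_config")
}

repertoire_frame <- function(repertoire) {
  tab <- repertoire$table
  wit <- vapply(seq_len(nrow(tab)), function(i) {
    r <- repertoire$results[[i]]
    if (is.null(r$witness)) "" else
      paste(sprintf("%s=%.6g", names(r$witness), r$witness), collapse = ";")
  }, "")
  cbind(tab, witness = wit, stringsAsFactors = FALSE)
}

#' Write a phenotypic repertoire to CSV or JSON
#'
#' Columns: case number, case signature, status, maximal slack and the
#' slack-maximizing witness parameters.
#'
#' @param repertoire a `phenotypic_repertoire`.
#' @param path output path.
#' @param seed optional seed to record (JSON only).
#' @return Invisibly, the path.
#' @export
write_repertoire_csv <- function(repertoire, path) {
  utils::write.csv(repertoire_frame(repertoire), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_repertoire_csv
#' @export
write_repertoire_json <- function(repertoire, path, seed = NULL) {
  payload <- list(
    schema_version = "1.0",
    eps_slack = repertoire$eps_slack,
    seed = seed,
    bounds = as.data.frame(t(repertoire$bounds)),
    phenotypic_fraction = list(valid = length(repertoire$valid_cases),
                               total = nrow(repertoire$table)),
    cases = repertoire_frame(repertoire))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a per-case stability table to CSV
#'
#' @param dynamics named list of `case_dynamics` (names are case numbers),
#'   e.g. one design's entry of [screen_designs()] details.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_stability_csv <- function(dynamics, path) {
  df <- do.call(rbind, lapply(names(dynamics), function(k) {
    d <- dynamics[[k]]
    data.frame(case_number = as.integer(k), n_positive = d$n_positive,
               class = d$class, oscillatory_potential = d$oscillatory_potential,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
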