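#' Two-dimensional slice of design space
#'
#' A slice fixes all but two log10 parameters and spans the remaining two
#' over ranges, to be rasterized into a region/stability map.
#'
#' @param x_param,y_param axis parameter names (distinct).
#' @param x_range,y_range length-2 log10 ranges.
#' @param fixed named vector (linear scale) of all remaining parameters.
#' @param resolution grid resolution per axis (default 301).
#' @return An object of class `slice`.
#' @export
design_slice <- function(x_param, y_param, x_range, y_range, fixed,
                         resolution = 301L) {
  stopifnot(x_param != y_param, length(x_range) == 2, length(y_range) == 2,
            diff(x_range) > 0, diff(y_range) > 0)
  structure(list(x_param = x_param, y_param = y_param,
                 x_range = as.numeric(x_range), y_range = as.numeric(y_range),
                 fixed = fixed, resolution = as.integer(resolution)),
            class = "slice")
}

# precompute per-valid-case affine maps once for point/grid queries
case_cache <- function(system, repertoire) {
  compiled <- compile_gma(system)
  sys_sig <- compute_system_signature(system)
  lapply(repertoire$valid_cases, function(n) {
    m <- case_maps(system, number_to_signature(n, sys_sig), compiled)
    m$case_number <- n
    m
  })
}

#' Cases whose regions contain a parameter point
#'
#' For each valid case of the repertoire, evaluates the case's dominance
#' rows at the point (no LP) and reports the case if all rows hold with
#' strictly positive margin, together with the eigenvalue count of its
#' reduced Jacobian there.  Multiple members indicate coexisting fixed
#' points (e.g. bistability).
#'
#' @param system a [gma_system()].
#' @param repertoire a [enumerate_repertoire()] result for `system`.
#' @param point named parameter vector (linear scale).
#' @param cache optional precomputed internal case cache.
#' @return Data frame with columns `case_number`, `margin`, `n_positive`,
#'   `has_unstable_focus`.
#' @export
cases_at_point <- function(system, repertoire, point, cache = NULL) {
  if (is.null(cache)) cache <- case_cache(system, repertoire)
  znames <- cache[[1]]$znames %||% colnames(system$bounds)
  z <- log10_point(point, znames)
  rows <- lapply(cache, function(m) {
    if (!m$solvable) return(NULL)
    marg <- if (nrow(m$W)) min(drop(m$W %*% z + m$w0)) else Inf
    if (marg <= 0) return(NULL)
    phi <- 10^drop(m$L0 + m$LZ %*% z)
    es <- if (is.null(m$K_reduced)) NULL else phi_eigen(phi, m$K_reduced)
    data.frame(case_number = m$case_number, margin = marg,
               n_positive = if (is.null(es)) NA_integer_ else es$n_positive,
               has_unstable_focus = if (is.null(es)) NA else es$has_unstable_focus)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(case_number = integer(0), margin = numeric(0),
                      n_positive = integer(0), has_unstable_focus = logical(0))
  out
}

# Fig-2 style color classes from the per-point case set
slice_color_class <- function(npos, focus) {
  k <- length(npos)
  npos <- unname(sort(as.integer(npos)))
  if (k == 1L && npos == 0L) return("monostable")
  if (k == 1L && npos == 2L && isTRUE(focus)) return("unstable_focus")
  if (k == 3L && identical(npos, c(0L, 0L, 1L))) return("bistable")
  if (k == 3L && identical(npos, c(0L, 1L, 2L))) return("mixed")
  "other"
}

#' Rasterize a design-space slice
#'
#' Evaluates every valid case's dominance rows over the grid (the rows are
#' affine in the two axis coordinates, so each region is read off directly)
#' and, where a case is present, the eigenvalue count of its reduced
#' Jacobian.  Each grid point is assigned a color class: `monostable`
#' (single stable case, blue), `bistable` (three cases with eigenvalue
#' counts 0/0/1, red), `unstable_focus` (single case with a complex pair
#' with positive real parts, yellow), `mixed` (three cases 0/1/2, orange),
#' `other` (grey).
#'
#' @param system a [gma_system()].
#' @param repertoire its [enumerate_repertoire()] result.
#' @param slice a [design_slice()].
#' @return An object of class `slice_map`: `x`, `y` (log10 grids), `cases`
#'   (list of case-number matrices is avoided: a list of presence matrices
#'   keyed by case), `npos` (list of eigencount matrices), `class`
#'   (character matrix), plus the slice.
#' @export
rasterize_slice <- function(system, repertoire, slice) {
  stopifnot(inherits(slice, "slice"))
  cache <- case_cache(system, repertoire)
  znames <- colnames(system$bounds)
  xs <- seq(slice$x_range[1], slice$x_range[2], length.out = slice$resolution)
  ys <- seq(slice$y_range[1], slice$y_range[2], length.out = slice$resolution)
  fixed_names <- setdiff(znames, c(slice$x_param, slice$y_param))
  zf <- log10_point(slice$fixed, fixed_names)
  nx <- length(xs); ny <- length(ys)
  pres <- list(); npos <- list(); focus <- list()
  for (m in cache) {
    if (!m$solvable) next
    key <- as.character(m$case_number)
    cst <- drop(m$W[, fixed_names, drop = FALSE] %*% zf) + m$w0
    wx <- m$W[, slice$x_param]; wy <- m$W[, slice$y_param]
    P <- matrix(TRUE, nx, ny)
    for (r in seq_along(cst))
      P <- P & (outer(wx[r] * xs, wy[r] * ys, `+`) + cst[r] > 0)
    if (!any(P)) next
    pres[[key]] <- P
    # eigen counts where present
    l_cst <- drop(m$LZ[, fixed_names, drop = FALSE] %*% zf) + m$L0
    lx <- m$LZ[, slice$x_param]; ly <- m$LZ[, slice$y_param]
    NP <- matrix(NA_integer_, nx, ny); FC <- matrix(NA, nx, ny)
    idx <- which(P, arr.ind = TRUE)
    for (t in seq_len(nrow(idx))) {
      i <- idx[t, 1]; j <- idx[t, 2]
      phi <- 10^(l_cst + lx * xs[i] + ly * ys[j])
      es <- phi_eigen(phi, m$K_reduced)
      NP[i, j] <- es$n_positive; FC[i, j] <- es$has_unstable_focus
    }
    npos[[key]] <- NP; focus[[key]] <- FC
  }
  cls <- matrix("other", nx, ny)
  keys <- names(pres)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    here <- keys[vapply(keys, function(k) pres[[k]][i, j], TRUE)]
    if (!length(here)) { cls[i, j] <- "empty"; next }
    cls[i, j] <- slice_color_class(
      vapply(here, function(k) npos[[k]][i, j], 1L),
      any(vapply(here, function(k) focus[[k]][i, j], TRUE)))
  }
  structure(list(x = xs, y = ys, presence = pres, npos = npos, focus = focus,
                 class = cls, slice = slice),
            class = "slice_map")
}

#' @export
print.slice_map <- function(x, ...) {
  tab <- table(x$class)
  cat(sprintf("Slice map %dx%d over (%s, %s); classes: %s\n",
              length(x$x), length(x$y), x$slice$x_param, x$slice$y_param,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat("  cases present:", paste(names(x$presence), collapse = ", "), "\n")
  invisible(x)
}

slice_palette <- c(monostable = "#3b6fb6", bistable = "#c23b3b",
                   unstable_focus = "#e8c832", mixed = "#e08b3a",
                   other = "#9b9b9b", empty = "#ffffff")

#' Plot a slice map with the standard color convention
#'
#' Blue monostable, red bistable, yellow unstable focus, orange mixed,
#' grey other.
#'
#' @param x a `slice_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.slice_map <- function(x, ...) {
  lev <- names(slice_palette)
  z <- matrix(match(x$class, lev), length(x$x), length(x$y))
  graphics::image(x$x, x$y, z, col = slice_palette, zlim = c(1, length(lev)),
                  xlab = paste0("log10 ", x$slice$x_param),
                  ylab = paste0("log10 ", x$slice$y_param), ...)
  invisible(x)
}

#' Write a slice map to CSV (long format) or PNG
#'
#' @param map a `slice_map`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_slice_csv <- function(map, path) {
  keys <- names(map$presence)
  grid <- expand.grid(i = seq_along(map$x), j = seq_along(map$y))
  cases <- vapply(seq_len(nrow(grid)), function(t) {
    i <- grid$i[t]; j <- grid$j[t]
    paste(keys[vapply(keys, function(k) map$presence[[k]][i, j], TRUE)],
          collapse = ";")
  }, "")
  df <- data.frame(x = map$x[grid$i], y = map$y[grid$j], cases = cases,
                   class = map$class[cbind(grid$i, grid$j)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_slice_csv
#' @export
write_slice_png <- function(map, path) {
  grDevices::png(path, width = 900, height = 800)
  on.exit(grDevices::dev.off())
  plot(map)
  invisible(path)
}
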