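#' Fit the core linear map of a replicate
#'
#' Re-expresses the quantile normalization of a replicate's core as a linear
#' map: ordinary least squares of the mean grid (response) on the
#' replicate's own grid (predictor) over the grid points gives an intercept
#' `a` and slope `b` that can then be applied to every value in the core,
#' not just the grid points.
#'
#' A degenerate grid (zero variance, e.g. when the core collapses onto a
#' single value, as happens when all positive controls yield zero reads)
#' cannot support a regression; the fit falls back to pure centering
#' (`b = 1`, `a = mean(mean_grid) - mean(grid)`) with a warning.
#'
#' @param grid The replicate's quantile grid (from [quantile_grid()]).
#' @param mean_grid The across-replicate mean grid (from
#'   [mean_quantile_grid()]), same length.
#' @param core The replicate's core-set entry (one element of a `core_set`),
#'   providing the core bounds.
#' @param tail_mode `"shift"` (default) or `"literal"`; stored on the map
#'   and used by [apply_linear_map()].
#' @return A `piecewise_map`: list with `a`, `b`, `z_min`, `z_max`,
#'   `tail_mode`, `degenerate`.
#' @export
fit_linear_map <- function(grid, mean_grid, core,
                           tail_mode = c("shift", "literal")) {
  tail_mode <- match.arg(tail_mode)
  stopifnot(length(grid) == length(mean_grid))
  vx <- stats::var(grid)
  degenerate <- !is.finite(vx) || vx <= 0
  if (degenerate) {
    warning("zero-variance quantile grid; falling back to pure centering")
    b <- 1
    a <- mean(mean_grid) - mean(grid)
  } else {
    b <- stats::cov(grid, mean_grid) / vx
    a <- mean(mean_grid) - b * mean(grid)
  }
  structure(list(a = a, b = b, z_min = core$z_min, z_max = core$z_max,
                 tail_mode = tail_mode, degenerate = degenerate),
            class = "piecewise_map")
}

#' Apply a piecewise-linear normalization map
#'
#' Values inside the core bounds are mapped linearly,
#' \eqn{z^{\mathrm{norm}} = a + b z}. Values beyond a bound are shifted by
#' the same amount as the bound itself, preserving their distance to the
#' core and hence the replicate's tail heaviness:
#' \eqn{a + (b - 1)z^{\max} + z} above the core, and (default `"shift"`
#' mode) \eqn{a + (b - 1)z^{\min} + z} below it. Both pieces are continuous
#' at the bounds and, for \eqn{b > 0}, strictly increasing.
#'
#' `tail_mode = "literal"` instead uses \eqn{a + (b + 1)z^{\min} - z} below
#' the core: a reflection of the lower tail, also continuous at
#' \eqn{z^{\min}}, kept for strict compatibility with the published formula
#' but not order-preserving.
#'
#' @param map A `piecewise_map` from [fit_linear_map()].
#' @param z Numeric vector of lethality scores (library features and
#'   controls alike are transformed with the same map).
#' @return Numeric vector of normalized scores.
#' @export
apply_linear_map <- function(map, z) {
  stopifnot(inherits(map, "piecewise_map"))
  a <- map$a; b <- map$b
  out <- a + b * z
  hi <- z > map$z_max
  out[hi] <- a + (b - 1) * map$z_max + z[hi]
  lo <- z < map$z_min
  if (map$tail_mode == "shift") {
    out[lo] <- a + (b - 1) * map$z_min + z[lo]
  } else {
    out[lo] <- a + (b + 1) * map$z_min - z[lo]
  }
  out
}

#' @export
print.piecewise_map <- function(x, ...) {
  cat(sprintf("piecewise_map: z' = %.4g + %.4g z on [%.4g, %.4g], tails %s%s\n",
              x$a, x$b, x$z_min, x$z_max, x$tail_mode,
              if (x$degenerate) " (degenerate fallback)" else ""))
  invisible(x)
}
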