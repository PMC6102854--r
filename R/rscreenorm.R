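#' Control-anchored piecewise-linear normalization
#'
#' Runs the full normalization pipeline on a multi-replicate screen:
#'
#' 1. optional readout transform ([transform_readout()]);
#' 2. lethality scoring against the assay controls
#'    ([lethality_scores()]), per replicate or per plate;
#' 3. core-set selection per replicate ([select_core_percentile()] or
#'    [select_core_distance()]);
#' 4. quantile-grid representation of each core and averaging across
#'    replicates ([quantile_grid()], [mean_quantile_grid()]);
#' 5. per-replicate linear map fitted on the grids ([fit_linear_map()]) and
#'    applied piecewise to all scores ([apply_linear_map()]), extending the
#'    core normalization to the tails as pure shifts.
#'
#' The result aligns the core of the score distributions across replicates
#' while leaving each replicate's tail proportions intact, so screens with
#' genuinely more lethal hits keep their heavier upper tail.
#'
#' Grids are built from library-feature core values only; control scores are
#' transformed with the fitted maps but never drive them.
#'
#' @param x A [screen_study()] (raw readouts; steps 1–2 apply) or a
#'   `lethality_scores` object (already on the anchored scale, e.g.
#'   simulated scores; steps 1–2 are skipped).
#' @param transform,pseudocount Passed to [transform_readout()] when `x` is
#'   a `screen_study`.
#' @param scope Scoring scope for [lethality_scores()]:
#'   `"replicate"` or `"plate"`.
#' @param core_method `"percentile"` (default) or `"distance"`.
#' @param alpha_high,alpha_low Percentile-core parameters; scalars or named
#'   per-replicate vectors.
#' @param gamma Distance-core parameter.
#' @param tail_mode `"shift"` (default, order-preserving) or `"literal"`.
#' @param n_quantiles Grid length, default 1000.
#' @return An object of class `rscreenorm`: a list with
#'   \describe{
#'     \item{scores}{data frame with `lethality_score`, `rscreenorm_score`
#'       and `in_core` columns appended to the study annotations;}
#'     \item{maps}{data frame of fitted parameters per replicate
#'       (`a`, `b`, `z_min`, `z_max`, core size, selection parameters);}
#'     \item{mean_grid}{the reference quantile grid.}
#'   }
#' @examples
#' set.seed(1)
#' sim <- simulate_study(sim_config(n_cell_lines = 2, reps_per_line = 2,
#'                                  n_features = 200, n_neg = 20, n_pos = 20))
#' fit <- rscreenorm(sim$scores)
#' fit$maps
#' @export
rscreenorm <- function(x,
                       transform = c("identity", "log2", "asinh", "negate"),
                       pseudocount = 0,
                       scope = c("replicate", "plate"),
                       core_method = c("percentile", "distance"),
                       alpha_high = 0.95, alpha_low = 0, gamma = 1,
                       tail_mode = c("shift", "literal"),
                       n_quantiles = 1000) {
  transform <- match.arg(transform)
  scope <- match.arg(scope)
  core_method <- match.arg(core_method)
  tail_mode <- match.arg(tail_mode)

  if (inherits(x, "screen_study")) {
    x <- transform_readout(x, kind = transform, pseudocount = pseudocount)
    scores <- lethality_scores(x, scope = scope)
  } else if (inherits(x, "lethality_scores")) {
    scores <- x
  } else {
    stop("x must be a screen_study or lethality_scores object")
  }

  core <- switch(core_method,
    percentile = select_core_percentile(scores, alpha_high = alpha_high,
                                        alpha_low = alpha_low),
    distance = select_core_distance(scores, gamma = gamma)
  )

  reps <- names(core)
  grids <- lapply(core, function(cs) quantile_grid(cs$values, n_quantiles))
  mg <- mean_quantile_grid(grids)
  maps <- lapply(reps, function(r) {
    fit_linear_map(grids[[r]], mg, core[[r]], tail_mode = tail_mode)
  })
  names(maps) <- reps

  out <- scores
  names(out)[names(out) == "score"] <- "lethality_score"
  out$rscreenorm_score <- NA_real_
  out$in_core <- FALSE
  for (r in reps) {
    idx <- out$replicate == r
    m <- maps[[r]]
    out$rscreenorm_score[idx] <- apply_linear_map(m, out$lethality_score[idx])
    out$in_core[idx] <- out$lethality_score[idx] >= m$z_min &
      out$lethality_score[idx] <= m$z_max & out$well_type[idx] == "library"
  }
  class(out) <- "data.frame"

  par_name <- if (core_method == "percentile") "alpha_low" else "gamma"
  map_df <- data.frame(
    replicate = reps,
    a = vapply(maps, `[[`, numeric(1), "a"),
    b = vapply(maps, `[[`, numeric(1), "b"),
    z_min = vapply(maps, `[[`, numeric(1), "z_min"),
    z_max = vapply(maps, `[[`, numeric(1), "z_max"),
    core_size = vapply(core, function(cs) length(cs$values), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (core_method == "percentile") {
    map_df$alpha_high <- vapply(core, function(cs) cs$params$alpha_high, numeric(1))
    map_df$alpha_low <- vapply(core, function(cs) cs$params$alpha_low, numeric(1))
  } else {
    map_df$gamma <- gamma
  }

  structure(list(scores = out, maps = map_df, mean_grid = mg,
                 fitted_maps = maps,
                 config = list(transform = transform, scope = scope,
                               core_method = core_method,
                               alpha_high = alpha_high, alpha_low = alpha_low,
                               gamma = gamma, tail_mode = tail_mode,
                               n_quantiles = n_quantiles)),
            class = "rscreenorm")
}

#' @export
print.rscreenorm <- function(x, ...) {
  cat("rscreenorm fit: ", nrow(x$maps), " replicate(s), core method '",
      x$config$core_method, "', tails '", x$config$tail_mode, "'\n", sep = "")
  print(x$maps, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn rscreenorm Density overlay of library-feature score
#'   distributions before (lethality scores) and after normalization, one
#'   curve per replicate.
#' @param ... Unused.
#' @export
plot.rscreenorm <- function(x, ...) {
  lib <- x$scores[x$scores$well_type == "library", ]
  reps <- unique(lib$replicate)
  cols <- grDevices::hcl.colors(max(3L, length(reps)), "Dark 3")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (col_name in c("lethality_score", "rscreenorm_score")) {
    dens <- lapply(reps, function(r) stats::density(lib[[col_name]][lib$replicate == r]))
    graphics::plot(NA, xlim = range(sapply(dens, function(d) range(d$x))),
                   ylim = c(0, max(sapply(dens, function(d) max(d$y)))),
                   xlab = sub("_", " ", col_name), ylab = "density",
                   main = if (col_name == "lethality_score") "before" else "after")
    for (i in seq_along(dens)) graphics::lines(dens[[i]], col = cols[i])
  }
  invisible(x)
}

#' Write normalized scores and fitted parameters
#'
#' Writes the per-well score table (and optionally the per-replicate fitted
#' map parameters) as tab-separated files with the package's standard
#' column layout.
#'
#' @param fit An `rscreenorm` object.
#' @param path Output path for the score table.
#' @param maps_path Optional output path for the fitted-parameter table.
#' @return `fit`, invisibly.
#' @export
write_rscreenorm <- function(fit, path, maps_path = NULL) {
  stopifnot(inherits(fit, "rscreenorm"))
  sc <- fit$scores
  cols <- intersect(c("feature_id", "well_type", "cell_line", "replicate",
                      "plate", "lethality_score", "rscreenorm_score",
                      "in_core"), names(sc))
  utils::write.table(sc[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(maps_path)) {
    utils::write.table(fit$maps, maps_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fit)
}
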