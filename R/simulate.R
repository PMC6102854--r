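#' Simulation configuration for synthetic multi-cell-line screens
#'
#' Defines the generative model used throughout the package's evaluation
#' harness: several cell lines screened in technical triplicate, library
#' features and assay controls drawn on the lethality-score scale, a
#' per-cell-line stretch/contraction of the functional range, and an
#' optional group effect on a fixed fraction of features.
#'
#' Per replicate, negative controls are Normal(0, `ctrl_sd`), positive
#' controls Normal(1, `ctrl_sd`), and library feature \eqn{i} is
#' Normal(\eqn{\mu_i}, `feature_sd`) with \eqn{\mu_i \sim
#' \mathrm{Beta}(2, 6)} (expectation 1/4: most features yield little
#' lethality). The stretch multiplies the *means* of library features and
#' positive controls by the cell line's factor (negative-control means are
#' 0, so they are untouched); `pos_bias` adds to positive-control means.
#' The default factors 0.7/1/1.4 are balanced across the two cell-line
#' groups, making the stretch orthogonal to the group effect.
#'
#' @param n_cell_lines Number of cell lines (default 6).
#' @param reps_per_line Technical replicates per line (default 3).
#' @param n_features Library features per replicate (default 1000).
#' @param n_neg,n_pos Controls per replicate (default 200 each).
#' @param ctrl_sd,feature_sd Normal standard deviations (0.1, 0.2).
#' @param beta_shape Length-2 shape of the feature-mean Beta distribution,
#'   default `c(2, 6)`.
#' @param stretch_factors Per-cell-line mean multipliers; default
#'   `c(0.7, 1, 1.4, 0.7, 1, 1.4)`.
#' @param effect_fraction Fraction of features carrying the group effect in
#'   with-effect mode (default 0.2); deterministically the first
#'   `round(effect_fraction * n_features)` features.
#' @param effect_mean Mean of effect features in the affected lines (0.5).
#' @param effect_lines Cell lines (indices) carrying the effect,
#'   default `4:6`.
#' @param pos_bias Per-cell-line additive bias on positive-control means,
#'   default all 0.
#' @param mu_per_replicate Draw \eqn{\mu_i} independently per replicate
#'   (`TRUE`) instead of once per feature shared across replicates
#'   (default `FALSE`).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cell_lines = 6, reps_per_line = 3,
                       n_features = 1000, n_neg = 200, n_pos = 200,
                       ctrl_sd = 0.1, feature_sd = 0.2,
                       beta_shape = c(2, 6),
                       stretch_factors = rep(c(0.7, 1, 1.4),
                                             length.out = n_cell_lines),
                       effect_fraction = 0.2, effect_mean = 0.5,
                       effect_lines = seq(n_cell_lines %/% 2 + 1, n_cell_lines),
                       pos_bias = rep(0, n_cell_lines),
                       mu_per_replicate = FALSE) {
  cfg <- list(n_cell_lines = n_cell_lines, reps_per_line = reps_per_line,
              n_features = n_features, n_neg = n_neg, n_pos = n_pos,
              ctrl_sd = ctrl_sd, feature_sd = feature_sd,
              beta_shape = beta_shape, stretch_factors = stretch_factors,
              effect_fraction = effect_fraction, effect_mean = effect_mean,
              effect_lines = effect_lines, pos_bias = pos_bias,
              mu_per_replicate = mu_per_replicate)
  stopifnot(n_cell_lines >= 1, reps_per_line >= 1, n_features >= 1,
            n_neg >= 1, n_pos >= 1,
            ctrl_sd > 0, feature_sd > 0,
            length(beta_shape) == 2, all(beta_shape > 0),
            length(stretch_factors) == n_cell_lines,
            effect_fraction >= 0, effect_fraction <= 1,
            all(effect_lines %in% seq_len(n_cell_lines)),
            length(pos_bias) == n_cell_lines)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-cell-line screen on the lethality-score scale
#'
#' Draws one synthetic study under a [sim_config()]: all values are
#' generated directly as lethality scores (anchored controls near 0 and 1),
#' so normalization is applied from the core-selection step onward without
#' re-anchoring.
#'
#' @param config A [sim_config()].
#' @param mode `"no_effect"` (all features null) or `"with_effect"`
#'   (the first `effect_fraction * n_features` features have mean
#'   `effect_mean` in the `effect_lines`).
#' @return A list of class `simulated_study`:
#'   \describe{
#'     \item{scores}{`lethality_scores` long table
#'       (`n_cell_lines * reps_per_line` replicates, features plus
#'       controls);}
#'     \item{truth}{logical vector over features, `TRUE` for effect
#'       features (all `FALSE` in no-effect mode);}
#'     \item{mu}{the realized feature means (matrix features x replicates,
#'       before stretching);}
#'     \item{design}{replicate-level data frame with `replicate`,
#'       `cell_line`, `group` (`TRUE` for effect lines).}
#'   }
#' @export
simulate_study <- function(config = sim_config(),
                           mode = c("no_effect", "with_effect")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_cell_lines * config$reps_per_line
  nf <- config$n_features
  line_of_rep <- rep(seq_len(config$n_cell_lines), each = config$reps_per_line)
  rep_ids <- paste0("line", line_of_rep, "_r",
                    rep(seq_len(config$reps_per_line), config$n_cell_lines))
  feat_ids <- sprintf("f%04d", seq_len(nf))

  n_eff <- round(config$effect_fraction * nf)
  truth <- rep(FALSE, nf)
  if (mode == "with_effect" && n_eff > 0) truth[seq_len(n_eff)] <- TRUE

  if (config$mu_per_replicate) {
    mu <- matrix(stats::rbeta(nf * K, config$beta_shape[1], config$beta_shape[2]),
                 nf, K)
  } else {
    mu <- matrix(stats::rbeta(nf, config$beta_shape[1], config$beta_shape[2]),
                 nf, K)
  }
  dimnames(mu) <- list(feat_ids, rep_ids)

  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    line <- line_of_rep[k]
    s <- config$stretch_factors[line]
    mu_k <- mu[, k]
    if (mode == "with_effect" && line %in% config$effect_lines) {
      mu_k[truth] <- config$effect_mean
    }
    feat <- stats::rnorm(nf, mean = s * mu_k, sd = config$feature_sd)
    neg <- stats::rnorm(config$n_neg, mean = 0, sd = config$ctrl_sd)
    pos <- stats::rnorm(config$n_pos,
                        mean = s * 1 + config$pos_bias[line],
                        sd = config$ctrl_sd)
    blocks[[k]] <- data.frame(
      feature_id = c(feat_ids,
                     sprintf("neg%03d", seq_len(config$n_neg)),
                     sprintf("pos%03d", seq_len(config$n_pos))),
      well_type = c(rep("library", nf),
                    rep("neg_control", config$n_neg),
                    rep("pos_control", config$n_pos)),
      cell_line = paste0("line", line),
      replicate = rep_ids[k],
      score = c(feat, neg, pos),
      stringsAsFactors = FALSE)
  }
  scores <- as_lethality_scores(do.call(rbind, blocks))
  design <- data.frame(replicate = rep_ids,
                       cell_line = paste0("line", line_of_rep),
                       group = line_of_rep %in% config$effect_lines,
                       stringsAsFactors = FALSE)
  structure(list(scores = scores, truth = stats::setNames(truth, feat_ids),
                 mu = mu, design = design, mode = mode, config = config),
            class = "simulated_study")
}

#' False-discovery / power experiment across normalization methods
#'
#' Repeatedly simulates studies, normalizes each with the requested
#' methods, tests every feature for a group effect (effect lines versus the
#' rest) with [per_feature_test()], adjusts with Benjamini-Hochberg, and
#' records the false-discovery proportion (and, in with-effect mode, the
#' true-positive proportion among effect features) per dataset and method.
#'
#' @param n_datasets Number of simulated datasets.
#' @param config A [sim_config()].
#' @param mode `"no_effect"` or `"with_effect"`.
#' @param methods Subset of `c("none", "rscreenorm", "classic_qn",
#'   "robust_z", "median_center")`.
#' @param level FDR control level, default 0.05.
#' @param alpha_high Core percentile used by the `"rscreenorm"` method,
#'   default 0.95.
#' @return A list of class `fdr_experiment` with `per_dataset` (long data
#'   frame: dataset, method, fdp, tpp, n_discoveries) and `summary`
#'   (per-method mean, sd and Monte-Carlo standard error of fdp and tpp).
#' @export
run_fdr_experiment <- function(n_datasets, config = sim_config(),
                               mode = c("no_effect", "with_effect"),
                               methods = c("none", "rscreenorm"),
                               level = 0.05, alpha_high = 0.95) {
  mode <- match.arg(mode)
  methods <- match.arg(methods,
                       c("none", "rscreenorm", "classic_qn", "robust_z",
                         "median_center"), several.ok = TRUE)
  stopifnot(n_datasets >= 1)
  rows <- vector("list", n_datasets * length(methods))
  ri <- 0L
  for (d in seq_len(n_datasets)) {
    sim <- simulate_study(config, mode)
    for (meth in methods) {
      norm <- if (meth == "rscreenorm") {
        normalize_screen(sim$scores, method = meth, alpha_high = alpha_high)
      } else {
        normalize_screen(sim$scores, method = meth)
      }
      ht <- per_feature_test(norm, sim$design, level = level)
      fdp <- false_discovery_proportion(ht$significant,
                                        sim$truth[ht$feature_id])
      tpp <- if (any(sim$truth)) {
        sum(ht$significant & sim$truth[ht$feature_id]) / sum(sim$truth)
      } else NA_real_
      ri <- ri + 1L
      rows[[ri]] <- data.frame(dataset = d, method = meth, fdp = fdp,
                               tpp = tpp, n_discoveries = sum(ht$significant),
                               stringsAsFactors = FALSE)
    }
  }
  per_dataset <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_dataset, per_dataset$method),
    function(s) data.frame(
      method = s$method[1],
      mean_fdp = mean(s$fdp), sd_fdp = stats::sd(s$fdp),
      mcse_fdp = stats::sd(s$fdp) / sqrt(nrow(s)),
      mean_tpp = mean(s$tpp), sd_tpp = stats::sd(s$tpp),
      stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(per_dataset = per_dataset, summary = summ,
                 mode = mode, level = level, n_datasets = n_datasets),
            class = "fdr_experiment")
}

#' @export
print.fdr_experiment <- function(x, ...) {
  cat("fdr_experiment: ", x$n_datasets, " datasets, mode '", x$mode,
      "', level ", x$level, "\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Simulate an arrayed screen with additive plate effects
#'
#' Raw-readout fixture generator for plate-effect behaviour: a single
#' replicate laid out over several plates, where every well of plate
#' \eqn{p} receives the additive offset \eqn{\delta_p}. Per-plate lethality
#' scoring removes such offsets exactly; per-replicate scoring does not.
#'
#' @param n_plates Number of plates.
#' @param wells_per_plate Library wells per plate.
#' @param plate_offsets Numeric vector of length `n_plates`.
#' @param n_neg,n_pos Controls per plate (minimum 2 each).
#' @param ctrl_sd,feature_sd Readout noise standard deviations.
#' @param base_neg,base_pos Plate-free control readout levels.
#' @return A [screen_study()] with plate annotation.
#' @export
simulate_arrayed_plates <- function(n_plates, wells_per_plate, plate_offsets,
                                    n_neg = 4, n_pos = 4,
                                    ctrl_sd = 0.1, feature_sd = 0.2,
                                    base_neg = 1, base_pos = 0.2) {
  stopifnot(n_plates >= 1, length(plate_offsets) == n_plates,
            n_neg >= 2, n_pos >= 2, wells_per_plate >= 1)
  blocks <- lapply(seq_len(n_plates), function(p) {
    d <- plate_offsets[p]
    mu <- stats::runif(wells_per_plate, base_pos, base_neg)
    data.frame(
      feature_id = c(sprintf("p%d_w%03d", p, seq_len(wells_per_plate)),
                     sprintf("p%d_neg%d", p, seq_len(n_neg)),
                     sprintf("p%d_pos%d", p, seq_len(n_pos))),
      well_type = c(rep("library", wells_per_plate),
                    rep("neg_control", n_neg), rep("pos_control", n_pos)),
      cell_line = "simline", replicate = "simline_r1",
      plate = paste0("plate", p),
      readout = d + c(stats::rnorm(wells_per_plate, mu, feature_sd),
                      stats::rnorm(n_neg, base_neg, ctrl_sd),
                      stats::rnorm(n_pos, base_pos, ctrl_sd)),
      stringsAsFactors = FALSE)
  })
  screen_study(do.call(rbind, blocks))
}
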