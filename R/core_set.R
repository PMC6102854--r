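#' Select a core set of score values by percentile
#'
#' Per replicate, the core set is the multiset of library lethality-score
#' *values* (not feature ids) lying between the `alpha_low` and `alpha_high`
#' empirical quantiles of that replicate's library scores. Excluding the
#' upper tail (and optionally the lower one, when increased-proliferation
#' phenotypes are expected) keeps differential hit proportions out of the
#' normalization: only the part of the distribution assumed common to all
#' screens is aligned.
#'
#' With `alpha_high = 1` and `alpha_low = 0` the core is the full score set.
#' For genome-wide screens of untreated cell lines, 0.90–0.95 is a sensible
#' upper cut; under treatments expected to enlarge the lethal fraction, a
#' lower `alpha_high` for the treated lines is appropriate. Per-replicate
#' values may be supplied as a named vector.
#'
#' Ties at the quantile boundary are included: all copies of a qualifying
#' value enter the core.
#'
#' @param scores A `lethality_scores` object.
#' @param alpha_high Upper percentile in (0, 1], default 0.95. Scalar or a
#'   named vector keyed by replicate.
#' @param alpha_low Lower percentile in [0, 1), default 0. Scalar or named
#'   vector.
#' @return A `core_set`: a list with one element per replicate, each holding
#'   `values` (the selected score multiset), `z_min`, `z_max` and the
#'   selection parameters.
#' @export
select_core_percentile <- function(scores, alpha_high = 0.95, alpha_low = 0) {
  stopifnot(inherits(scores, "lethality_scores"))
  reps <- unique(scores$replicate)
  a_hi <- expand_per_replicate(alpha_high, reps, "alpha_high")
  a_lo <- expand_per_replicate(alpha_low, reps, "alpha_low")
  if (any(a_hi <= 0 | a_hi > 1)) stop("alpha_high must be in (0, 1]")
  if (any(a_lo < 0 | a_lo >= 1)) stop("alpha_low must be in [0, 1)")
  if (any(a_lo >= a_hi)) stop("alpha_low must be < alpha_high")

  out <- lapply(reps, function(r) {
    v <- scores$score[scores$replicate == r & scores$well_type == "library"]
    hi <- stats::quantile(v, a_hi[[r]], type = 7, names = FALSE)
    lo <- if (a_lo[[r]] > 0) stats::quantile(v, a_lo[[r]], type = 7, names = FALSE)
          else -Inf
    core <- v[v >= lo & v <= hi]
    if (!length(core)) stop("empty core set for replicate ", r)
    list(values = core, z_min = min(core), z_max = max(core),
         params = list(method = "percentile",
                       alpha_high = a_hi[[r]], alpha_low = a_lo[[r]]))
  })
  names(out) <- reps
  structure(out, class = "core_set")
}

#' Select a core set by distance to the assay controls
#'
#' Alternative core rule for studies where no natural percentile presents
#' itself: a score value enters the core when it is close enough to the
#' negative controls relative to the positive ones,
#' \eqn{|v - m_N| \le \gamma\,|v - m_P|}, with \eqn{m_N}, \eqn{m_P} the
#' replicate's scored control medians (0 and 1 when scores were anchored in
#' that replicate). With `gamma = 1` this keeps the values closer to the
#' negative than to the positive controls; larger `gamma` admits more of the
#' lethal range, and in the limit all finite scores.
#'
#' @param scores A `lethality_scores` object (control records must be
#'   present, as they define the anchors).
#' @param gamma Positive scalar; boundary values are included.
#' @return A `core_set` (see [select_core_percentile()]).
#' @export
select_core_distance <- function(scores, gamma = 1) {
  stopifnot(inherits(scores, "lethality_scores"), gamma > 0)
  reps <- unique(scores$replicate)
  out <- lapply(reps, function(r) {
    idx <- scores$replicate == r
    m_n <- stats::median(scores$score[idx & scores$well_type == "neg_control"])
    m_p <- stats::median(scores$score[idx & scores$well_type == "pos_control"])
    v <- scores$score[idx & scores$well_type == "library"]
    core <- v[abs(v - m_n) <= gamma * abs(v - m_p)]
    if (!length(core)) stop("empty core set for replicate ", r)
    list(values = core, z_min = min(core), z_max = max(core),
         params = list(method = "distance", gamma = gamma))
  })
  names(out) <- reps
  structure(out, class = "core_set")
}

expand_per_replicate <- function(x, reps, what) {
  if (length(x) == 1 && is.null(names(x))) {
    return(stats::setNames(rep(as.numeric(x), length(reps)), reps))
  }
  miss <- setdiff(reps, names(x))
  if (length(miss)) {
    stop(what, " given per replicate but missing for: ",
         paste(miss, collapse = ", "))
  }
  stats::setNames(as.numeric(x[reps]), reps)
}

#' @export
print.core_set <- function(x, ...) {
  cat("core_set over ", length(x), " replicate(s)\n", sep = "")
  for (r in names(x)) {
    cat(sprintf("  %s: %d values in [%.4g, %.4g]\n", r,
                length(x[[r]]$values), x[[r]]$z_min, x[[r]]$z_max))
  }
  invisible(x)
}

#' Empirical quantile grid of a value set
#'
#' Represents a core set of arbitrary size by a fixed grid of empirical
#' quantiles at probabilities \eqn{j/n,\ j = 1, \dots, n} (default
#' \eqn{n = 1000}), which makes differently sized core sets comparable.
#' Quantiles use linear interpolation between order statistics at position
#' \eqn{h = (m - 1)p + 1} (the common statistical default); \eqn{p = 1}
#' returns the maximum.
#'
#' @param values Numeric vector (a core set's values), nonempty.
#' @param n_quantiles Grid length, default 1000.
#' @return Nondecreasing numeric vector of length `n_quantiles`.
#' @export
quantile_grid <- function(values, n_quantiles = 1000) {
  stopifnot(length(values) >= 1, n_quantiles >= 1)
  stats::quantile(values, probs = seq_len(n_quantiles) / n_quantiles,
                  type = 7, names = FALSE)
}

#' Average quantile grids across replicates
#'
#' The reference distribution for core-restricted quantile normalization:
#' each grid point is replaced by its mean over all replicate grids.
#'
#' @param grids A list of equal-length quantile grids, or a matrix with one
#'   column per replicate.
#' @return Numeric vector: the elementwise mean grid.
#' @export
mean_quantile_grid <- function(grids) {
  if (is.list(grids)) {
    len <- unique(lengths(grids))
    if (length(len) != 1) stop("grids must all have the same length")
    grids <- matrix(unlist(grids), nrow = len[1])
  }
  rowMeans(grids)
}
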