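#' Robust z-scores per replicate
#'
#' The common screen-by-screen standardization that ignores assay controls:
#' per replicate, center at the median of the library features and scale by
#' their (by default normal-consistent) median absolute deviation,
#' \eqn{z = (x - \mathrm{med})/(1.4826\,\mathrm{MAD})}. Controls are
#' transformed with the center and scale fitted on the library features.
#'
#' @param scores A `lethality_scores` object (any per-replicate score
#'   table; the method itself does not use the anchoring).
#' @param scaled Use the 1.4826 consistency factor (default); `FALSE` for
#'   raw MAD.
#' @return A `lethality_scores` object with transformed scores; attribute
#'   `"method"` set to `"robust_z"`.
#' @export
robust_z <- function(scores, scaled = TRUE) {
  stopifnot(inherits(scores, "lethality_scores"))
  const <- if (scaled) 1.4826 else 1
  for (r in unique(scores$replicate)) {
    idx <- scores$replicate == r
    lib <- scores$score[idx & scores$well_type == "library"]
    ctr <- stats::median(lib)
    scl <- const * stats::mad(lib, constant = 1)
    if (scl == 0) stop("MAD is zero for replicate ", r)
    scores$score[idx] <- (scores$score[idx] - ctr) / scl
  }
  attr(scores, "method") <- "robust_z"
  scores
}

#' Median-centering per replicate
#'
#' Subtracts each replicate's library-feature median from all its values —
#' the pre-processing step used by common pooled-screen pipelines. Controls
#' are shifted by the same amount.
#'
#' @param scores A `lethality_scores` object.
#' @return A `lethality_scores` object with centered scores; attribute
#'   `"method"` set to `"median_center"`.
#' @export
median_center <- function(scores) {
  stopifnot(inherits(scores, "lethality_scores"))
  for (r in unique(scores$replicate)) {
    idx <- scores$replicate == r
    ctr <- stats::median(scores$score[idx & scores$well_type == "library"])
    scores$score[idx] <- scores$score[idx] - ctr
  }
  attr(scores, "method") <- "median_center"
  scores
}

#' Classic full-range quantile normalization
#'
#' Standard quantile normalization of a complete features-by-replicates
#' matrix: each column's order statistics are replaced by the row means of
#' the column-sorted matrix; ties within a column receive the mean of their
#' positions' reference values. This forces *every* quantile — tails
#' included — to agree across replicates, which is exactly the behaviour
#' the core-restricted method avoids: genuinely different proportions of
#' lethal phenotypes are equalized away.
#'
#' @param x Numeric matrix, features in rows, replicates in columns
#'   (complete; no missing values).
#' @return Matrix of the same shape with identical column distributions.
#' @export
classic_quantile_normalize <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x), !anyNA(x))
  if (ncol(x) == 1) return(x)
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    v <- numeric(length(col))
    v[order(col)] <- ref
    # tied values share the mean of the reference values at their positions
    stats::ave(v, col)
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Apply a normalization method to a score table
#'
#' Uniform front-end used by the evaluation harness: dispatches a long
#' `lethality_scores` table to one of the package's normalization methods
#' and returns a table of the same shape.
#'
#' `"classic_qn"` pivots the library features to a complete
#' features-by-replicates matrix (all replicates must share the feature
#' set), normalizes, and maps values back; control wells are left unchanged
#' by it (the method is defined on the library matrix only).
#'
#' @param scores A `lethality_scores` object.
#' @param method One of `"none"`, `"rscreenorm"`, `"robust_z"`,
#'   `"median_center"`, `"classic_qn"`.
#' @param ... Passed on to [rscreenorm()] or [robust_z()].
#' @return A `lethality_scores` object with normalized scores.
#' @export
normalize_screen <- function(scores,
                             method = c("none", "rscreenorm", "robust_z",
                                        "median_center", "classic_qn"),
                             ...) {
  method <- match.arg(method)
  stopifnot(inherits(scores, "lethality_scores"))
  out <- switch(method,
    none = scores,
    rscreenorm = {
      fit <- rscreenorm(scores, ...)
      sc <- fit$scores
      sc$score <- sc$rscreenorm_score
      sc$lethality_score <- sc$rscreenorm_score <- sc$in_core <- NULL
      as_lethality_scores(sc)
    },
    robust_z = robust_z(scores, ...),
    median_center = median_center(scores),
    classic_qn = {
      m <- scores_to_matrix(scores)
      n <- classic_quantile_normalize(m)
      lib <- scores$well_type == "library"
      scores$score[lib] <- n[cbind(match(scores$feature_id[lib], rownames(n)),
                                   match(scores$replicate[lib], colnames(n)))]
      scores
    }
  )
  attr(out, "method") <- method
  out
}

#' Pivot library-feature scores to a matrix
#'
#' @param scores A `lethality_scores` object whose replicates all measured
#'   the same library features exactly once.
#' @return Numeric matrix, features in rows (named), replicates in columns.
#' @export
scores_to_matrix <- function(scores) {
  stopifnot(inherits(scores, "lethality_scores"))
  lib <- scores[scores$well_type == "library", ]
  feats <- unique(lib$feature_id)
  reps <- unique(lib$replicate)
  m <- matrix(NA_real_, length(feats), length(reps),
              dimnames = list(feats, reps))
  m[cbind(match(lib$feature_id, feats), match(lib$replicate, reps))] <- lib$score
  if (anyNA(m)) stop("library features are not complete across replicates")
  m
}
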