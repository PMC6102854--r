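#' Compute lethality scores
#'
#' Standardizes readouts against the assay controls of their own scoring
#' scope. For a library feature \eqn{i} in replicate \eqn{k},
#' \deqn{Z_{ik} = \frac{x_{ik} - \mathrm{med}(Z^N_k)}{\mathrm{med}(Z^P_k) - \mathrm{med}(Z^N_k)},}
#' where \eqn{Z^N_k} and \eqn{Z^P_k} are the negative- and positive-control
#' readouts of the scope. A readout at the negative-control median scores 0
#' (normal viability); one at the positive-control median scores 1 (as
#' lethal as the positive controls). The formula is orientation-free: if
#' lower readouts mean more lethality the denominator is negative and signs
#' cancel.
#'
#' With `scope = "plate"` the control medians are taken per plate within
#' each replicate, which removes additive plate effects exactly (every well
#' on a plate shares the offset, and the numerator subtracts it while the
#' denominator is offset-invariant).
#'
#' Controls are scored with the same formula and retained: they anchor the
#' scale (their own scope medians map to exactly 0 and 1) and are carried
#' through normalization.
#'
#' @param study A [screen_study()] (transform readouts first if needed).
#' @param scope `"replicate"` (default) or `"plate"`.
#' @param tol Minimum absolute difference between positive- and
#'   negative-control medians; a scope below this has no usable functional
#'   range and is an error.
#' @return A data frame of class `lethality_scores`: the study columns with
#'   `readout` replaced by `score`.
#' @examples
#' st <- screen_study(data.frame(
#'   feature_id = c("g1", "n1", "n2", "p1", "p2"),
#'   well_type = c("library", "neg_control", "neg_control",
#'                 "pos_control", "pos_control"),
#'   cell_line = "A", replicate = "A_1",
#'   readout = c(6, 10, 10, 2, 2)
#' ))
#' lethality_scores(st)$score  # (6-10)/(2-10) = 0.5 for g1
#' @export
lethality_scores <- function(study, scope = c("replicate", "plate"),
                             tol = 1e-8) {
  scope <- match.arg(scope)
  stopifnot(inherits(study, "screen_study"))
  if (scope == "plate") {
    if (!("plate" %in% names(study)) || all(is.na(study$plate))) {
      stop("scope = 'plate' requires plate annotation")
    }
    key <- paste(study$replicate, study$plate, sep = "\r")
  } else {
    key <- study$replicate
  }
  score <- numeric(nrow(study))
  for (sc in unique(key)) {
    idx <- key == sc
    neg <- study$readout[idx & study$well_type == "neg_control"]
    pos <- study$readout[idx & study$well_type == "pos_control"]
    label <- gsub("\r", "/", sc)
    if (!length(neg) || !length(pos)) {
      stop("scope ", label, " lacks negative or positive controls")
    }
    m_n <- stats::median(neg)
    m_p <- stats::median(pos)
    if (abs(m_p - m_n) <= tol) {
      stop("degenerate functional range in scope ", label,
           ": |median(pos) - median(neg)| = ", format(abs(m_p - m_n)),
           " <= ", tol)
    }
    score[idx] <- (study$readout[idx] - m_n) / (m_p - m_n)
  }
  out <- study
  out$readout <- NULL
  out$score <- score
  class(out) <- c("lethality_scores", "data.frame")
  out
}

#' Treat existing values as lethality scores
#'
#' Marks a long-format table whose values are already on the lethality-score
#' scale (negative controls near 0, positive controls near 1) so that core
#' selection and normalization can be applied without re-anchoring. This is
#' the natural entry point for simulated studies, which are generated
#' directly on the score scale.
#'
#' @param x A data frame with columns `feature_id`, `well_type`,
#'   `cell_line`, `replicate`, `score` (and optionally `plate`).
#' @return `x` with class `lethality_scores`.
#' @export
as_lethality_scores <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("feature_id", "well_type", "cell_line", "replicate",
                  "score") %in% names(x)))
  if (any(!is.finite(x$score))) stop("non-finite score value(s)")
  bad <- setdiff(unique(x$well_type), WELL_TYPES)
  if (length(bad)) stop("unknown well_type value(s): ", paste(bad, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  class(x) <- c("lethality_scores", "data.frame")
  x
}

#' @export
print.lethality_scores <- function(x, ...) {
  cat("lethality_scores: ", nrow(x), " records, ",
      length(unique(x$replicate)), " replicate(s)\n", sep = "")
  lib <- x$score[x$well_type == "library"]
  cat("  library score range: [", format(min(lib), digits = 4), ", ",
      format(max(lib), digits = 4), "]\n", sep = "")
  invisible(x)
}
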