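#' Per-feature group test
#'
#' For every library feature, fits ordinary least squares of the normalized
#' score on a replicate-level design (a two-level group factor plus optional
#' covariates) and tests the group coefficient with a two-sided Student's
#' t-test. All features share the design matrix, so the fit is vectorized
#' through one QR decomposition.
#'
#' `moderation = "pooled"` shrinks each feature's residual variance toward
#' the across-feature mean residual variance with weight
#' \eqn{\mathrm{df}/(\mathrm{df} + d_0)}:
#' \eqn{\tilde s_i^2 = (\mathrm{df}\, s_i^2 + d_0 \bar{s}^2)/(\mathrm{df} + d_0)},
#' and tests on \eqn{\mathrm{df} + d_0} degrees of freedom — a deliberately
#' simple moderated-variance option, not a full empirical-Bayes fit.
#'
#' Conventions for degenerate features: a zero estimate with zero residual
#' variance yields \eqn{t = 0, p = 1}; a nonzero estimate with zero residual
#' variance (unmoderated) yields a missing p-value and a `flagged` mark.
#'
#' @param scores A `lethality_scores` object (library features are tested),
#'   or a features-by-replicates matrix with column names matching
#'   `design$replicate`.
#' @param design Data frame with columns `replicate` and `group` (two
#'   levels; the tested contrast), plus any further columns that
#'   `covariates` may name.
#' @param covariates Character vector of design columns to adjust for
#'   (default none).
#' @param moderation `"none"` (default) or `"pooled"`.
#' @param d0 Prior degrees of freedom for pooled moderation, default 4.
#' @param level FDR level for the significance flag, default 0.05.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A `hit_table` data frame: `feature_id`, `estimate`, `se`, `t`,
#'   `df`, `p`, `p_adjusted` (Benjamini-Hochberg), `significant`, `flagged`.
#' @export
per_feature_test <- function(scores, design, covariates = character(0),
                             moderation = c("none", "pooled"), d0 = 4,
                             level = 0.05,
                             alternative = c("two.sided", "greater", "less")) {
  moderation <- match.arg(moderation)
  alternative <- match.arg(alternative)
  stopifnot(is.data.frame(design),
            all(c("replicate", "group") %in% names(design)))

  m <- if (is.matrix(scores)) scores else scores_to_matrix(scores)
  i <- match(colnames(m), design$replicate)
  if (anyNA(i)) {
    stop("replicate(s) missing from design: ",
         paste(colnames(m)[is.na(i)], collapse = ", "))
  }
  design <- design[i, , drop = FALSE]
  grp <- factor(design$group)
  if (nlevels(grp) != 2) stop("design$group must have exactly two levels")
  if (any(table(grp) < 2)) stop("need >= 2 replicates per group")
  miss_cov <- setdiff(covariates, names(design))
  if (length(miss_cov)) {
    stop("covariate(s) not in design: ", paste(miss_cov, collapse = ", "))
  }
  X <- stats::model.matrix(
    ~ ., data = cbind(data.frame(group = grp), design[covariates]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is not full rank")
  df <- ncol(m) - ncol(X)
  if (df < 1) stop("no residual degrees of freedom")

  coefs <- qr.coef(qrX, t(m))                # p x n_features
  resid <- t(m) - X %*% coefs
  s2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  j <- 2L                                    # the group coefficient
  est <- coefs[j, ]
  if (moderation == "pooled") {
    s2 <- (df * s2 + d0 * mean(s2)) / (df + d0)
    df_t <- df + d0
  } else {
    df_t <- df
  }
  # numerically zero residual variance / estimate, relative to data scale
  scale2 <- colMeans(t(m)^2)
  zero_var <- s2 <= scale2 * 1e-24
  zero_est <- abs(est) <= sqrt(scale2) * 1e-12
  se <- sqrt(s2 * XtXinv[j, j])
  t_stat <- est / se
  flagged <- rep(FALSE, length(est))
  t_stat[zero_var & zero_est] <- 0
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(t_stat), df_t),
    greater = stats::pt(t_stat, df_t, lower.tail = FALSE),
    less = stats::pt(t_stat, df_t)
  )
  bad <- zero_var & !zero_est
  p[bad] <- NA_real_
  flagged[bad] <- TRUE

  adj <- bh_adjust(p, level = level)
  out <- data.frame(feature_id = rownames(m), estimate = est, se = se,
                    t = t_stat, df = df_t, p = p,
                    p_adjusted = adj$adjusted, significant = adj$significant,
                    flagged = flagged,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1) via
#' [stats::p.adjust()], plus the flags at the requested control level.
#' Missing p-values propagate to missing adjusted values and `FALSE` flags.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @param level FDR control level, default 0.05.
#' @return List with `adjusted` and logical `significant`.
#' @export
bh_adjust <- function(p, level = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted,
       significant = !is.na(adjusted) & adjusted <= level)
}

#' False-discovery proportion
#'
#' Share of discoveries that are false, \eqn{V / \max(R, 1)}: 0 by
#' convention when nothing is discovered.
#'
#' @param flags Logical vector of rejections.
#' @param truth Logical vector, `TRUE` for genuinely non-null features.
#' @return A number in \[0, 1\].
#' @export
false_discovery_proportion <- function(flags, truth) {
  stopifnot(length(flags) == length(truth))
  r <- sum(flags)
  if (r == 0) return(0)
  sum(flags & !truth) / r
}

#' Concordance between two hit tables
#'
#' Cross-tabulates significance calls of two analyses of a shared feature
#' set (typically a primary screen and a validation screen) and reports the
#' reproducibility summaries:
#' * `agreement` — same conclusion in both, \eqn{(SS + NN)/\mathrm{total}};
#' * `discordance` — opposite conclusions, \eqn{(SN + NS)/\mathrm{total}};
#' * `hit_confirmation` — fraction of A's hits confirmed in B;
#' * `ns_confirmation` — fraction of A's non-hits also non-hits in B;
#' * `ns_overlap_union` / `ns_overlap_total` — non-hit overlap measured
#'   against the union of non-hit sets and against the common total
#'   (both conventions are reported and labelled).
#'
#' Agreement and discordance are symmetric in the two tables; the
#' confirmation fractions condition on table A.
#'
#' @param table_a,table_b `hit_table` objects (or data frames with
#'   `feature_id` and `significant`). The feature intersection is used; its
#'   size is reported.
#' @return An object of class `concordance_summary`.
#' @export
concordance <- function(table_a, table_b) {
  stopifnot(all(c("feature_id", "significant") %in% names(table_a)),
            all(c("feature_id", "significant") %in% names(table_b)))
  common <- intersect(table_a$feature_id, table_b$feature_id)
  if (!length(common)) stop("no features in common")
  a <- table_a$significant[match(common, table_a$feature_id)]
  b <- table_b$significant[match(common, table_b$feature_id)]
  n <- length(common)
  ss <- sum(a & b); nn <- sum(!a & !b)
  sn <- sum(a & !b); ns <- sum(!a & b)
  out <- list(
    n_common = n,
    counts = c(SS = ss, SN = sn, NS = ns, NN = nn),
    agreement = (ss + nn) / n,
    discordance = (sn + ns) / n,
    hit_confirmation = if (ss + sn > 0) ss / (ss + sn) else NA_real_,
    ns_confirmation = if (nn + ns > 0) nn / (nn + ns) else NA_real_,
    ns_overlap_union = if (nn + sn + ns > 0) nn / (nn + sn + ns) else NA_real_,
    ns_overlap_total = nn / n
  )
  class(out) <- "concordance_summary"
  out
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("concordance over", x$n_common, "common features\n")
  cat(sprintf("  counts: S&S=%d S&NS=%d NS&S=%d NS&NS=%d\n",
              x$counts["SS"], x$counts["SN"], x$counts["NS"], x$counts["NN"]))
  cat(sprintf("  agreement %.1f%%, discordance %.1f%%\n",
              100 * x$agreement, 100 * x$discordance))
  cat(sprintf("  hit confirmation %.1f%%, non-hit confirmation %.1f%%\n",
              100 * x$hit_confirmation, 100 * x$ns_confirmation))
  invisible(x)
}
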