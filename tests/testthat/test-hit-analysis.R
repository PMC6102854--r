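make_design <- function(reps, group) {
  data.frame(replicate = reps, group = group, stringsAsFactors = FALSE)
}

test_that("the vectorized group test matches per-feature lm()", {
  set.seed(801)
  m <- matrix(rnorm(8 * 20), 20, 8,
              dimnames = list(sprintf("f%02d", 1:20), paste0("r", 1:8)))
  des <- make_design(paste0("r", 1:8), rep(c("a", "b"), each = 4))
  des$time <- rep(c(1, 2), 4)

  ht <- per_feature_test(m, des, covariates = "time")
  for (i in c(1, 7, 20)) {
    fit <- summary(lm(m[i, ] ~ factor(des$group) + des$time))
    expect_equal(ht$estimate[i], unname(fit$coefficients[2, 1]))
    expect_equal(ht$se[i], unname(fit$coefficients[2, 2]))
    expect_equal(ht$p[i], unname(fit$coefficients[2, 4]))
    expect_equal(ht$df[i], fit$df[2])
  }
})

test_that("degenerate features follow the stated conventions", {
  m <- rbind(flat = rep(1, 6),
             split = c(1, 1, 1, 2, 2, 2),
             noisy = c(0.9, 1.1, 1.0, 1.9, 2.2, 2.0))
  colnames(m) <- paste0("r", 1:6)
  des <- make_design(paste0("r", 1:6), rep(c("a", "b"), each = 3))
  ht <- per_feature_test(m, des)
  # identical values in both groups: estimate 0, p = 1
  expect_equal(ht$estimate[ht$feature_id == "flat"], 0)
  expect_equal(ht$p[ht$feature_id == "flat"], 1)
  expect_false(ht$flagged[ht$feature_id == "flat"])
  # nonzero difference with zero residual variance: missing p, flagged
  expect_true(is.na(ht$p[ht$feature_id == "split"]))
  expect_true(ht$flagged[ht$feature_id == "split"])
  expect_false(is.na(ht$p[ht$feature_id == "noisy"]))
})

test_that("a strong separation is detected and label permutation is symmetric", {
  set.seed(802)
  x <- c(rnorm(9, 0, 0.1), rnorm(9, 10, 0.1))
  m <- matrix(x, 1, 18, dimnames = list("f1", paste0("r", 1:18)))
  des <- make_design(paste0("r", 1:18), rep(c("a", "b"), each = 9))
  ht <- per_feature_test(m, des)
  expect_lt(ht$p, 1e-6)

  flipped <- des
  flipped$group <- rev(des$group)
  ht2 <- per_feature_test(m, flipped, level = 0.05)
  expect_equal(ht2$p, ht$p)
  expect_equal(ht2$estimate, -ht$estimate)
})

test_that("pooled moderation shrinks variances toward their mean", {
  set.seed(803)
  m <- matrix(rnorm(200 * 10, sd = rep(c(0.2, 2), each = 5)), 200, 10,
              byrow = TRUE,
              dimnames = list(sprintf("f%03d", 1:200), paste0("r", 1:10)))
  des <- make_design(paste0("r", 1:10), rep(c("a", "b"), each = 5))
  plain <- per_feature_test(m, des, moderation = "none")
  mod <- per_feature_test(m, des, moderation = "pooled", d0 = 4)
  df <- unique(plain$df)
  s2 <- plain$se^2 / (2 / 5)          # residual variance from the SE
  s2_shrunk <- (df * s2 + 4 * mean(s2)) / (df + 4)
  expect_equal(mod$se^2 / (2 / 5), s2_shrunk, tolerance = 1e-12)
  expect_equal(unique(mod$df), df + 4)
  # ordering: small variances grow, large ones shrink
  expect_true(all(mod$se[s2 < mean(s2)] > plain$se[s2 < mean(s2)]))
  expect_true(all(mod$se[s2 > mean(s2)] < plain$se[s2 > mean(s2)]))
})

test_that("BH adjustment matches the step-up oracle and flags at level", {
  expect_equal(bh_adjust(rep(0.03, 7))$adjusted, rep(0.03, 7))
  expect_equal(bh_adjust(0.2)$adjusted, 0.2)
  p10 <- c(0.01, 0.02, 0.03, 0.04, 0.05, rep(0.9, 5))
  expect_equal(bh_adjust(p10)$adjusted[1], 0.1)

  set.seed(804)
  for (i in 1:25) {
    p <- round(runif(sample(1:6, 1)), 2)
    expect_equal(bh_adjust(p)$adjusted, bh_brute_force(p))
  }

  res <- bh_adjust(p10, level = 0.1)
  expect_identical(res$significant, res$adjusted <= 0.1)
  expect_true(all(res$adjusted >= p10))
  expect_error(bh_adjust(c(0.5, 1.2)), "p")
})

test_that("false discovery proportion follows the V/max(R,1) convention", {
  expect_equal(false_discovery_proportion(rep(FALSE, 5), rep(TRUE, 5)), 0)
  flags <- c(rep(TRUE, 5), rep(FALSE, 5))
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, rep(FALSE, 5))
  expect_equal(false_discovery_proportion(flags, truth), 0.4)
  expect_equal(false_discovery_proportion(c(TRUE, TRUE), c(FALSE, FALSE)), 1)
})

test_that("concordance cross-tabulates and is symmetric where it should be", {
  ta <- data.frame(feature_id = sprintf("f%02d", 1:10),
                   significant = rep(c(TRUE, FALSE), each = 5))
  expect_equal(concordance(ta, ta)$agreement, 1)
  expect_equal(concordance(ta, ta)$discordance, 0)

  tb <- ta
  tb$significant <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE,
                      FALSE, FALSE, FALSE)
  ab <- concordance(ta, tb)
  ba <- concordance(tb, ta)
  expect_equal(ab$agreement, ba$agreement)
  expect_equal(ab$discordance, ba$discordance)
  expect_equal(ab$agreement + ab$discordance, 1)
  # confirmation fractions condition on the first table
  expect_false(isTRUE(all.equal(ab$hit_confirmation, ba$hit_confirmation)))

  expect_error(concordance(ta, data.frame(feature_id = "zz",
                                          significant = TRUE)),
               "common")
})

test_that("published validation-screen cross-tabulations are reproduced", {
  # construct flag pairs realizing a 2x2 table: (primary, secondary) counts
  build_pair <- function(ss, sn, ns, nn) {
    n <- ss + sn + ns + nn
    ids <- sprintf("s%03d", seq_len(n))
    primary <- data.frame(feature_id = ids,
                          significant = rep(c(TRUE, TRUE, FALSE, FALSE),
                                            c(ss, sn, ns, nn)))
    secondary <- data.frame(feature_id = ids,
                            significant = rep(c(TRUE, FALSE, TRUE, FALSE),
                                              c(ss, sn, ns, nn)))
    concordance(primary, secondary)
  }
  # core-normalized data: 91 hits confirmed of 194, 78 of 111 non-hits
  rs <- build_pair(91, 103, 33, 78)
  expect_equal(rs$agreement, 169 / 305)
  expect_equal(rs$hit_confirmation, 91 / 194)
  expect_equal(rs$ns_confirmation, 78 / 111)
  # robust z-scores: 99 of 267 hits, 5 of 38 non-hits
  rz <- build_pair(99, 168, 33, 5)
  expect_equal(rz$agreement, 104 / 305)
  expect_equal(rz$hit_confirmation, 99 / 267)
  expect_equal(rz$ns_confirmation, 5 / 38)
})
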