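test_that("Hotelling T2 reduces to the squared pooled t for one variable", {
  set.seed(31)
  for (i in 1:5) {
    a <- matrix(rnorm(12, 1), ncol = 1)
    b <- matrix(rnorm(15), ncol = 1)
    ht <- hotelling_t2(a, b)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(ht$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(ht$p_raw, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Hotelling T2 degenerate and invariance properties hold", {
  set.seed(32)
  a <- matrix(rnorm(60), ncol = 4)
  ht0 <- hotelling_t2(a, a)
  expect_equal(ht0$statistic, 0)
  expect_equal(ht0$p_raw, 1)
  expect_equal(ht0$effect, 0)

  # invariant under any common full-rank affine transform
  b <- matrix(rnorm(48, 0.5), ncol = 4)
  A <- matrix(rnorm(16), 4, 4) + 4 * diag(4)
  shift <- rnorm(4)
  ht1 <- hotelling_t2(a, b)
  ht2 <- hotelling_t2(sweep(a %*% A, 2, shift, "+"),
                      sweep(b %*% A, 2, shift, "+"))
  expect_equal(ht2$statistic, ht1$statistic, tolerance = 1e-8)

  dup <- cbind(a[, 1], a[, 1])
  expect_error(hotelling_t2(dup, cbind(b[, 1], b[, 1])), "collinear")
  expect_error(hotelling_t2(matrix(rnorm(8), 2), matrix(rnorm(8), 2)),
               "too few subjects")
})

test_that("Cohen's d matches the pooled-SD oracle on printed summaries", {
  # pooled formula computed by hand:
  # sp^2 = (16*3.9^2 + 14*4.4^2)/30 = 17.14667, d = 5.3/4.140853 = 1.27993
  expect_equal(cohens_d_from_summary(16.6, 3.9, 17, 11.3, 4.4, 15),
               1.27993, tolerance = 1e-5)
  # sp^2 = (16*2.4^2 + 14*1.9^2)/30 = 4.756667, |d| = 2.2/2.180978 = 1.00872
  expect_equal(abs(cohens_d_from_summary(-5.5, 2.4, 17, -3.3, 1.9, 15)),
               1.00872, tolerance = 1e-5)

  set.seed(33)
  a <- rnorm(10); b <- rnorm(12)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_equal(cohens_d(a, a), 0)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "zero pooled")
})

test_that("pairwise comparisons honour the transform policy", {
  x <- c(1.2, 1.9, 2.4, 3.0, 3.3)
  same <- pairwise_compare(x, x, "none")
  expect_equal(same$p_raw, 1)
  expect_equal(same$effect, 0)

  # exact Mann-Whitney: U = 0, two-sided p = 2/choose(6,3) = 0.1
  mw <- pairwise_compare(c(1, 2, 3), c(4, 5, 6), "mann_whitney")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_raw, 0.1)
  expect_true(is.na(mw$effect))

  expect_error(pairwise_compare(c(0, 1, 2), c(1, 2, 3), "log"),
               "log transform undefined")

  # log policy equals a t-test on logs
  set.seed(34)
  a <- exp(rnorm(9)); b <- exp(rnorm(11, 0.6))
  lt <- pairwise_compare(a, b, "log")
  expect_equal(lt$p_raw, t.test(log(a), log(b), var.equal = TRUE)$p.value)
  expect_equal(lt$effect, cohens_d(log(a), log(b)))
})

test_that("normal approximation of the U test tracks the exact one", {
  set.seed(35)
  worst <- 0
  for (i in 1:40) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    p_exact <- wilcox.test(a, b, exact = TRUE)$p.value
    p_norm <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    worst <- max(worst, abs(p_exact - p_norm))
  }
  expect_lt(worst, 0.02)
})

test_that("Bonferroni adjustment is capped, scoped and order-preserving", {
  expect_equal(bonferroni_adjust(0.01, m = 5), 0.05)
  expect_equal(bonferroni_adjust(0.3, m = 5), 1)
  expect_identical(bonferroni_adjust(numeric(0)), numeric(0))
  p <- c(0.04, 0.001, 0.2)
  expect_equal(order(bonferroni_adjust(p, 9)), order(p))
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "smaller")
})

test_that("normality screen delegates to Shapiro-Wilk sensibly", {
  set.seed(36)
  hits <- mean(replicate(200, {
    normality_check(rexp(50))$decision == "non-normal"
  }))
  expect_gt(hits, 0.9)
  cover <- mean(replicate(400, {
    normality_check(rnorm(100))$decision == "normal"
  }))
  expect_gt(cover, 0.9)
  expect_error(normality_check(c(1, 2)), "between 3 and 5000")
})

test_that("family analysis wires families, transforms and adjustment together", {
  # feature-level cohort drawn directly from the published group summaries
  set.seed(37)
  draw_group <- function(gp, label) {
    n <- gp$n
    cols <- list(subject_id = sprintf("%s%02d", label, seq_len(n)), group = label)
    for (ch in c("o2hb", "hhb", "bfi")) for (nm in names(gp[[ch]])) {
      feat <- switch(paste(ch, nm),
        "o2hb base" = "ba_o2hb", "hhb base" = "ba_hhb", "bfi base" = "ba_bfi",
        "o2hb oc_slope" = "oc_d_o2hb_slope", "hhb oc_slope" = "oc_d_hhb_slope",
        "o2hb oc_min" = "oc_d_o2hb_min", "hhb oc_max" = "oc_d_hhb_max",
        "o2hb oc_tmin" = "oc_d_o2hb_tmin", "hhb oc_tmax" = "oc_d_hhb_tmax",
        "o2hb hy_max" = "hy_d_o2hb_max", "hhb hy_min" = "hy_d_hhb_min",
        "o2hb hy_tmax" = "hy_d_o2hb_tmax", "hhb hy_tmin" = "hy_d_hhb_tmin",
        "o2hb hy_htr" = "hy_d_o2hb_htr", "hhb hy_htr" = "hy_d_hhb_htr",
        "bfi oc_rbf_min" = "oc_rbf_min", "bfi hy_rbf_max" = "hy_rbf_max",
        "bfi hy_rbf_tmax" = "hy_rbf_tmax", "bfi hy_rbf_htr" = "hy_rbf_htr")
      cols[[feat]] <- pmax(rnorm(n, gp[[ch]][[nm]][1],
                                 max(gp[[ch]][[nm]][2], 0.02)),
                           if (feat %in% c("oc_rbf_min", "hy_rbf_max",
                                           "hy_rbf_htr", "ba_bfi")) 1e-3 else -Inf)
    }
    # emergent/analysis-only features, filled with plausible independent draws
    cols$ba_tsi <- rnorm(n, 63, 4); cols$oc_d_tsi_slope <- rnorm(n, -0.1, 0.05)
    cols$oc_d_tsi_min <- rnorm(n, -16, 6); cols$oc_d_tsi_tmin <- rnorm(n, -5, 4)
    cols$hy_d_tsi_max <- pmax(rnorm(n, 10, 4), 0.5)
    cols$hy_d_tsi_tmax <- rnorm(n, 23, 5); cols$hy_d_tsi_htr <- rnorm(n, 6, 2)
    cols$hy_d_o2hb_slope <- rnorm(n, 1.7, 0.6)
    cols$hy_d_hhb_slope <- rnorm(n, -1.4, 0.5)
    cols$hy_d_tsi_slope <- rnorm(n, 2, 0.7)
    cols$hy_rbf_slope <- pmax(rnorm(n, 80, 50), 5)
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  feats <- rbind(draw_group(reference_group_params("climber"), "climber"),
                 draw_group(reference_group_params("nonclimber"), "nonclimber"))
  rep <- run_family_analysis(feats)

  expect_setequal(rep$families$family, c("oc_nirs", "hy_nirs", "hy_dcs"))
  expect_equal(rep$families$df1[rep$families$family == "hy_nirs"], 12)
  expect_equal(nrow(rep$pairwise), 30)

  pw <- rep$pairwise
  expect_equal(pw$p_adj, pmin(1, pw$m * pw$p_raw))
  expect_equal(pw$m[pw$variable == "oc_d_o2hb_slope"], 9)
  expect_equal(pw$m[pw$variable == "hy_rbf_max"], 4)
  expect_equal(pw$transform[pw$variable == "hy_rbf_max"], "log")
  expect_equal(pw$test[pw$variable == "hy_rbf_htr"], "mann_whitney")

  # the lone occlusion DCS variable must equal a direct pairwise test
  direct <- pairwise_compare(feats$oc_rbf_min[feats$group == "climber"],
                             feats$oc_rbf_min[feats$group == "nonclimber"],
                             "log")
  row <- pw[pw$variable == "oc_rbf_min", ]
  expect_equal(row$p_raw, direct$p_raw)
  expect_equal(row$p_adj, direct$p_raw)  # family of size one
  expect_equal(row$d, direct$effect)
})

test_that("equal-parameter groups rarely reach family significance", {
  set.seed(38)
  rejections <- replicate(30, {
    a <- matrix(rnorm(17 * 4), ncol = 4)
    b <- matrix(rnorm(15 * 4), ncol = 4)
    hotelling_t2(a, b)$p_raw < 0.05
  })
  expect_lte(mean(rejections), 0.2)
})

test_that("the published hyperemia contrast is detectable at study sizes", {
  set.seed(39)
  hits <- replicate(60, {
    a <- rnorm(17, 16.6, 3.9); b <- rnorm(15, 11.3, 4.4)
    pairwise_compare(a, b, "none")$p_raw < 0.05
  })
  expect_gt(mean(hits), 0.5)
})
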