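test_that("rise constant realizes the requested half-time exactly", {
  # independent bisection oracle on the closed-form rise
  bisect_tau <- function(t_peak, htr) {
    f <- function(tau) (1 - exp(-htr / tau)) / (1 - exp(-t_peak / tau)) - 0.5
    lo <- 1e-3; hi <- 1e6
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    sqrt(lo * hi)
  }
  sol <- solve_rise_constant(14.4, 4.8)
  expect_false(sol$linear)
  expect_equal(sol$tau, bisect_tau(14.4, 4.8), tolerance = 1e-5)
  expect_equal(sol$tau, 10.04, tolerance = 0.01)  # one-third ratio kinetics

  # plug-back residual over a parameter grid
  for (tp in c(8, 14.4, 40)) for (frac in c(0.1, 0.25, 0.4, 0.48)) {
    s <- solve_rise_constant(tp, frac * tp)
    expect_false(s$linear)
    resid <- (1 - exp(-frac * tp / s$tau)) / (1 - exp(-tp / s$tau)) - 0.5
    expect_lt(abs(resid), 1e-6)
  }

  expect_true(solve_rise_constant(10, 5)$linear)
  expect_true(is.infinite(solve_rise_constant(10, 5)$tau))
  expect_error(solve_rise_constant(10, 0), "positive")
  expect_error(solve_rise_constant(10, 11), "precede")
})

test_that("trace simulation is deterministic and checks its inputs", {
  gt <- vot_ground_truth(seed = 99)
  r1 <- simulate_trace(gt)$recording
  r2 <- simulate_trace(gt)$recording
  expect_identical(r1$streams$O2HB$values, r2$streams$O2HB$values)
  expect_identical(r1$streams$BFI$values, r2$streams$BFI$values)

  bad <- vot_ground_truth(seed = 1)
  bad$o2hb$oc_tmin <- -400   # before inflation
  expect_error(simulate_trace(bad), "outside the occlusion")
  expect_error(vot_ground_truth(bfi = list(base = 1.7e-9, oc_rbf_min = 120,
                                           hy_rbf_max = 800, hy_rbf_tmax = 13,
                                           hy_rbf_htr = 5)),
               "floor")
  expect_error(vot_ground_truth(cardiac = list(freq = 0.5, amp_nirs = 1,
                                               amp_bfi_frac = 0.1)),
               "1.1 Hz")
})

test_that("cohort simulation is seed-reproducible and truncation-safe", {
  c1 <- simulate_cohort(seed = 5)
  c2 <- simulate_cohort(seed = 5)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$recordings[[1]]$streams$O2HB$values,
                   c2$recordings[[1]]$streams$O2HB$values)
  expect_equal(nrow(c1$truth), 32)
  expect_equal(sum(c1$truth$group == "climber"), 17)

  # zero-SD groups produce identical subjects
  degen <- reference_group_params("climber")
  degen$n <- 3
  for (ch in c("o2hb", "hhb", "bfi"))
    for (nm in names(degen[[ch]])) degen[[ch]][[nm]][2] <- 0
  cd <- simulate_cohort(degen, degen, seed = 6,
                        noise_sd = list(o2hb = 0, hhb = 0, bfi_frac = 0),
                        cardiac = list(freq = 1.2, amp_nirs = 0,
                                       amp_bfi_frac = 0))
  tt <- cd$truth[setdiff(names(cd$truth), c("subject_id", "group"))]
  expect_true(all(vapply(tt, function(col) max(col) - min(col), numeric(1)) == 0))
  f <- extract_cohort(lapply(cd$recordings[1:2], preprocess_recording))
  expect_equal(f[1, vot_feature_names], f[2, vot_feature_names],
               ignore_attr = TRUE)
})

test_that("cohort-level group contrasts behave like the study's", {
  co <- shared_cohort()
  feats <- co$features
  truth <- co$sim$truth
  # extracted cohort means track the generator's realized means
  for (v in c("hy_d_o2hb_max", "ba_o2hb", "oc_rbf_min")) {
    se <- sd(truth[[v]]) / sqrt(nrow(truth))
    expect_lt(abs(mean(feats[[v]]) - mean(truth[[v]])), 4 * se + 0.02)
  }
  # the headline oxygenation contrast points the right way
  d <- cohens_d(feats$hy_d_o2hb_max[feats$group == "climber"],
                feats$hy_d_o2hb_max[feats$group == "nonclimber"])
  expect_gt(d, 0)
})
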