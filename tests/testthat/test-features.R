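events_std <- cuff_events(t_inflate = 180, t_release = 480, end_time = 660,
                          t_contract = 175)

test_that("phase segmentation follows the baseline-placement policy", {
  w <- segment_phases(events_std)
  expect_equal(w$ba, c(105, 165))   # 15 s guard before inflation (contraction)
  expect_equal(w$oc, c(180, 480))
  expect_equal(w$hy, c(480, 660))

  no_contract <- cuff_events(180, 480, 660)
  expect_equal(segment_phases(no_contract)$ba, c(120, 180))

  expect_error(segment_phases(events_std, hy_window = 300),
               "hyperemia phase too short")
  expect_error(segment_phases(cuff_events(50, 480, 660)),
               "baseline phase too short")
})

test_that("baseline means average the window and police missingness", {
  rec <- flat_recording()
  w <- segment_phases(rec$events)
  base <- compute_baseline(rec, w)
  expect_equal(base$ba_o2hb, 43.6)
  expect_equal(base$ba_bfi, 1.7e-9)

  alt <- flat_recording()
  alt$streams$O2HB$values <- rep(c(1, 3), length.out = 6600)
  # closed window holds an odd sample count, so the mean is 2 up to one sample
  expect_equal(compute_baseline(alt, w)$ba_o2hb, 2, tolerance = 0.01)

  holey <- flat_recording()
  idx <- which(stream_times(holey$streams$O2HB) >= 105 &
               stream_times(holey$streams$O2HB) <= 165)
  holey$streams$O2HB$values[idx[seq_len(ceiling(0.3 * length(idx)))]] <- NA
  expect_error(compute_baseline(holey, w), "20%")
})

test_that("normalisation adds delta streams and relative blood flow", {
  rec <- flat_recording()
  w <- segment_phases(rec$events)
  base <- compute_baseline(rec, w)
  norm <- normalize_recording(rec, base)
  expect_true(all(norm$streams$RBF$values == 100))
  expect_true(all(norm$streams$D_O2HB$values == 0))

  rec$streams$O2HB$values[1] <- 39.1
  norm2 <- normalize_recording(rec, compute_baseline(rec, w))
  expect_equal(norm2$streams$D_O2HB$values[1],
               39.1 - mean(rec$streams$O2HB$values[idx <- which(
                 stream_times(rec$streams$O2HB) >= 105 &
                 stream_times(rec$streams$O2HB) <= 165)]))

  bad <- base
  bad$ba_bfi <- 0
  expect_error(normalize_recording(rec, bad), "non-positive baseline flow")
})

test_that("window slope is ordinary least squares on the samples", {
  s <- channel_stream("O2HB", c(0, 1, 2, 3, 4, 5), fs = 1)
  expect_equal(fit_window_slope(s, c(0, 5)), 1)
  s2 <- channel_stream("O2HB", c(0, 2, 3, 3, 5, 6.5), fs = 1)
  # closed-form OLS oracle
  tt <- 0:5
  expect_equal(fit_window_slope(s2, c(0, 5)),
               sum((tt - mean(tt)) * (s2$values - mean(s2$values))) /
                 sum((tt - mean(tt))^2))
  expect_equal(fit_window_slope(channel_stream("O2HB", rep(7, 9), fs = 1),
                                c(0, 8)), 0)
  expect_error(fit_window_slope(s, c(0, 3)), "underpopulated")
})

test_that("extrema use the release-relative sign convention and earliest tie", {
  v <- rep(0, 700)
  v[471] <- -4   # absolute 470 s at 1 Hz (t0 = 0)
  s <- channel_stream("O2HB", v, fs = 1)
  ext <- find_extremum(s, c(180, 480), "min", t_ref = 480)
  expect_equal(ext$value, -4)
  expect_equal(ext$time_rel, -10)

  v2 <- rep(0, 700); v2[c(495, 510)] <- 8  # plateau tie: earliest wins
  s2 <- channel_stream("O2HB", v2, fs = 1)
  ext2 <- find_extremum(s2, c(480, 660), "max", t_ref = 480)
  expect_equal(ext2$time_rel, 14)
  expect_error(find_extremum(channel_stream("O2HB", c(NA, NA), fs = 1),
                             c(0, 1), "max"), "no usable samples")
})

test_that("the occlusion RBF floor is the mean of the last pre-release 10 s", {
  rbf <- channel_stream("RBF", rep(12, 660), fs = 1, t0 = 0.5)
  expect_equal(oc_rbf_min(rbf, 480), 12)
  ramp <- channel_stream("RBF",
                         10 + 0.4 * (seq(0.5, by = 1, length.out = 660) - 470),
                         fs = 1, t0 = 0.5)
  # linear 10 -> 14 over the averaging window: mean 12
  expect_equal(oc_rbf_min(ramp, 480), 12)
  short <- channel_stream("RBF", rep(12, 100), fs = 1, t0 = 500)
  expect_error(oc_rbf_min(short, 480), "not covered")
})

test_that("half-time to recovery interpolates the half-height crossing", {
  up <- channel_stream("O2HB", c(rep(0, 481), seq(1, 10, length.out = 10),
                                 rep(10, 100)), fs = 1)
  ext <- find_extremum(up, c(480, 591), "max", t_ref = 480)
  expect_equal(compute_htr(up, 480, ext$value, ext$time_rel), 5)

  # saturating rise: closed-form HTR = tau * log(2)
  tau <- 8
  t <- seq(0, 120, by = 0.02)
  sat <- channel_stream("O2HB", c(rep(0, 480 * 50), 10 * (1 - exp(-t / tau))),
                        fs = 50)
  pk <- find_extremum(sat, c(480, 600), "max", t_ref = 480)
  expect_equal(compute_htr(sat, 480, pk$value, pk$time_rel), tau * log(2),
               tolerance = 1e-3)

  down <- channel_stream("HHB", c(rep(0, 481), seq(-0.5, -6, length.out = 12),
                                  rep(-6, 60)), fs = 1)
  pkd <- find_extremum(down, c(480, 553), "min", t_ref = 480)
  expect_equal(compute_htr(down, 480, pkd$value, pkd$time_rel), 6)

  flat <- channel_stream("O2HB", rep(2, 700), fs = 1)
  expect_error(compute_htr(flat, 480, 2, 50), "flat response")
})

test_that("hyperemic RBF slope is OLS from release to peak", {
  rbf <- channel_stream("RBF", c(rep(100, 480), seq(170, 800, by = 70),
                                 rep(100, 50)), fs = 1, t0 = 0.5)
  expect_equal(hy_rbf_slope(rbf, 480, 10), 70)
  expect_equal(hy_rbf_slope(channel_stream("RBF", rep(100, 660), fs = 1),
                            480, 20), 0)
  expect_error(hy_rbf_slope(rbf, 480, 1), "underpopulated")
})

test_that("feature extraction is shift-invariant and gain-covariant", {
  sim <- simulate_trace(quiet_truth())
  pre <- preprocess_recording(sim$recording)
  f0 <- unlist(extract_features(pre))

  shift <- 37.5
  shifted <- pre
  for (nm in names(shifted$streams)) shifted$streams[[nm]]$t0 <-
    shifted$streams[[nm]]$t0 + shift
  ev <- pre$events
  shifted$events <- cuff_events(ev$t_inflate + shift, ev$t_release + shift,
                                ev$end_time + shift, ev$t_contract + shift)
  f1 <- unlist(extract_features(shifted))
  expect_equal(f1, f0, tolerance = 1e-8)

  # doubling the O2Hb excursion around baseline doubles its slopes and
  # extrema but leaves its times and HTR unchanged
  gained <- pre
  ba <- mean(stream_window(pre$streams$O2HB, c(105, 165))$values)
  gained$streams$O2HB$values <- ba + 2 * (pre$streams$O2HB$values - ba)
  f2 <- unlist(extract_features(gained))
  for (nm in c("oc_d_o2hb_slope", "oc_d_o2hb_min", "hy_d_o2hb_max",
               "hy_d_o2hb_slope"))
    expect_equal(f2[[nm]], 2 * f0[[nm]], tolerance = 1e-6)
  for (nm in c("oc_d_o2hb_tmin", "hy_d_o2hb_tmax"))
    expect_equal(f2[[nm]], f0[[nm]], tolerance = 1e-8)
  expect_equal(f2[["hy_d_o2hb_htr"]], f0[["hy_d_o2hb_htr"]], tolerance = 0.05)
})

test_that("absent channels yield missing features, not failures", {
  sim <- simulate_trace(quiet_truth())
  rec <- sim$recording
  nirs_only <- vot_recording(rec$streams[c("O2HB", "HHB")], rec$events, rec$meta)
  f <- extract_features(preprocess_recording(nirs_only))
  expect_true(all(is.na(unlist(f[c("ba_bfi", "oc_rbf_min", "hy_rbf_max",
                                   "hy_rbf_tmax", "hy_rbf_slope", "hy_rbf_htr")]))))
  expect_false(anyNA(unlist(f[c("ba_o2hb", "oc_d_o2hb_slope", "hy_d_tsi_max")])))
})

test_that("a trace without hyperemic overshoot flags HTR instead of failing", {
  rec <- flat_recording()  # completely flat: zero response height everywhere
  rec$streams$BFI$values <- rec$streams$BFI$values *
    exp(-pmax(stream_times(rec$streams$BFI) - 180, 0) / 12) # collapse, no overshoot
  f <- extract_features(preprocess_recording(rec))
  expect_true(is.na(f$hy_d_o2hb_htr))
  expect_true(length(attr(f, "findings")) > 0)
})
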