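#' VOT protocol timing for the synthetic generator
#'
#' Default timing mirrors the standard cuff protocol: 3 min baseline ending
#' in a 5 s light contraction, rapid inflation, about 5 min of occlusion
#' (the point inside the 3-5 min stabilisation range), release, and 3 min of
#' recorded hyperemia. NIRS is sampled at 50 Hz and DCS at 38.5 Hz.
#'
#' @param ba_s,oc_s,hy_s Phase durations (s).
#' @param fs_nirs,fs_dcs Sampling rates (Hz).
#' @param contraction_s Light-contraction duration before inflation (s).
#' @return List of protocol timings, class `vot_protocol`.
#' @export
vot_protocol <- function(ba_s = 180, oc_s = 300, hy_s = 180,
                         fs_nirs = 50, fs_dcs = 38.5, contraction_s = 5) {
  structure(list(ba_s = ba_s, oc_s = oc_s, hy_s = hy_s, fs_nirs = fs_nirs,
                 fs_dcs = fs_dcs, contraction_s = contraction_s),
            class = "vot_protocol")
}

#' Rise time constant matching a prescribed half-time to recovery
#'
#' For the saturating-exponential hyperemic rise
#' `delta(t) = peak * (1 - exp(-t/tau)) / (1 - exp(-t_peak/tau))`,
#' finds `tau` such that half the peak height is reached exactly at `htr`.
#' A concave rise of this form always crosses half height before
#' `t_peak / 2`; at `htr = t_peak / 2` the shape degenerates to a straight
#' line (`tau -> Inf`), so requests at or beyond that limit return the
#' linear rise with a flag instead of failing.
#'
#' @param t_peak Time to peak (s).
#' @param htr Requested half-time to recovery (s), `0 < htr < t_peak`.
#' @return List with `tau` (s; `Inf` for the linear limit) and `linear`
#'   (logical flag).
#' @export
solve_rise_constant <- function(t_peak, htr) {
  if (!(htr > 0)) stop("htr must be positive", call. = FALSE)
  if (!(htr < t_peak)) stop("htr must precede t_peak", call. = FALSE)
  if (htr >= t_peak / 2 * (1 - 1e-9)) return(list(tau = Inf, linear = TRUE))
  half_frac <- function(lt) {
    tau <- exp(lt)
    (1 - exp(-htr / tau)) / (1 - exp(-t_peak / tau)) - 0.5
  }
  root <- stats::uniroot(half_frac, lower = log(t_peak * 1e-4),
                         upper = log(t_peak * 1e7), tol = 1e-13)
  list(tau = exp(root$root), linear = FALSE)
}

# --- internal continuous-trace machinery ------------------------------------
#
# Every synthetic extremum is built as a locally symmetric corner (equal
# approach and recede slope magnitudes) smoothed by a quadratic cap of
# half-width w. Symmetry matters: the zero-phase filter's symmetric kernel
# then leaves the extremum's time unmoved, and the cap's curvature is low
# enough that the value survives filtering essentially unchanged.

# Solve the hyperemic rise in a "rising frame" where the response goes up by
# h0 from release value to peak. The quadratic cap lowers the attainable
# edge height to h = h0 / (1 + lambda*w/2) (lambda = relative rise slope at
# the cap edge), and tau is solved on the capped geometry so the realized
# half-time equals the request exactly.
.solve_capped_rise <- function(h0, tp, htr, w) {
  tpw <- tp - w
  stopifnot(h0 > 0, tpw > 0)
  limit <- (tp - w / 2) / 2
  lam_of <- function(tau) exp(-tpw / tau) / (tau * (1 - exp(-tpw / tau)))
  if (htr >= limit * (1 - 1e-9)) {
    lam <- 1 / tpw
    h <- h0 / (1 + lam * w / 2)
    return(list(tau = Inf, h = h, kap = h * lam / (2 * w),
                htr = limit, linear = TRUE))
  }
  u_half <- function(lt) {
    tau <- exp(lt)
    q <- 1 - exp(-tpw / tau)
    h <- h0 / (1 + lam_of(tau) * w / 2)
    -tau * log(1 - (h0 / 2) / h * q) - htr
  }
  root <- stats::uniroot(u_half, lower = log(tp * 1e-4), upper = log(tp * 1e7),
                         tol = 1e-13)
  tau <- exp(root$root)
  h <- h0 / (1 + lam_of(tau) * w / 2)
  list(tau = tau, h = h, kap = h * lam_of(tau) / (2 * w), htr = htr,
       linear = FALSE)
}

# Hyperemic response as a function of time-since-release: saturating rise
# from v0, quadratic peak cap realizing exactly (peak, tp), then exponential
# relaxation toward relax_to with the departure slope matched to the
# approach slope (keeps the peak corner symmetric).
.hy_shape <- function(v0, peak, tp, htr, w, relax_to) {
  dir <- sign(peak - v0)
  if (dir == 0) stop("degenerate hyperemia: peak equals release value", call. = FALSE)
  sol <- .solve_capped_rise(abs(peak - v0), tp, htr, w)
  v0t <- dir * v0; pt <- dir * peak; rt <- dir * relax_to
  et <- pt - sol$kap * w^2
  if (!(et > rt))
    stop("hyperemic peak does not exceed the relaxation level", call. = FALSE)
  # relaxation: slope-matched to the rise (symmetric peak corner) but no
  # slower than the physiological recovery scale of about a minute, so weak
  # rises do not leave an unbounded post-peak plateau
  taur <- min((et - rt) / (2 * sol$kap * w), 60)
  tpw <- tp - w
  rho <- if (sol$linear) function(u) u / tpw else
    function(u) (1 - exp(-u / sol$tau)) / (1 - exp(-tpw / sol$tau))
  f <- function(u) {
    y <- rep(v0t, length(u))
    i <- u > 0 & u <= tpw
    y[i] <- v0t + sol$h * rho(u[i])
    i <- u > tpw & u <= tp + w
    y[i] <- pt - sol$kap * (u[i] - tp)^2
    i <- u > tp + w
    y[i] <- rt + (et - rt) * exp(-(u[i] - tp - w) / taur)
    dir * y
  }
  list(f = f, htr = sol$htr, linear = sol$linear)
}

# Occlusion drift of a chromophore delta as a function of time-since-
# inflation: exact linear segment at the 20-s slope, a gentler linear drift
# to the extremum, a symmetric quadratic cap realizing exactly (e, te), and
# a mirrored linear recovery until release.
.oc_shape <- function(s, e, te, oc_len, w, slope_win = 20) {
  dir <- sign(s)
  st <- abs(s); et_ <- dir * e
  if (!(et_ > slope_win * st))
    stop("occlusion extremum shallower than its initial slope implies", call. = FALSE)
  if (!(te - w > slope_win && te + w < oc_len))
    stop("extremum time outside the occlusion phase", call. = FALSE)
  # vertex above the target extremum so the cap's apex lands exactly on it
  vt <- (et_ - w * slope_win * st / (2 * (te - slope_win))) /
        (1 - w / (2 * (te - slope_win)))
  a <- (vt - slope_win * st) / (te - slope_win)
  f <- function(u) {
    y <- numeric(length(u))
    i <- u > 0 & u <= slope_win
    y[i] <- st * u[i]
    i <- u > slope_win & u <= te - w
    y[i] <- slope_win * st + a * (u[i] - slope_win)
    i <- abs(u - te) <= w
    y[i] <- vt - a * w / 2 - (a / (2 * w)) * (u[i] - te)^2
    i <- u > te + w
    y[i] <- vt - a * (u[i] - te)
    dir * y
  }
  list(f = f, a = a)
}

.dense_slope <- function(f, a, b, dt = 0.002) {
  t <- seq(a, b, by = dt)
  v <- f(t)
  tc <- t - mean(t)
  sum(tc * (v - mean(v))) / sum(tc * tc)
}

.dense_extremum <- function(f, a, b, mode, dt = 0.01) {
  t <- seq(a, b, by = dt)
  v <- f(t)
  k <- if (mode == "min") which.min(v) else which.max(v)
  if (k > 1L && k < length(v)) {  # parabolic refinement between grid points
    d2 <- v[k - 1L] - 2 * v[k] + v[k + 1L]
    if (abs(d2) > 1e-12) {
      off <- 0.5 * (v[k - 1L] - v[k + 1L]) / d2
      return(list(value = v[k] - 0.25 * (v[k - 1L] - v[k + 1L]) * off,
                  time = t[k] + off * dt))
    }
  }
  list(value = v[k], time = t[k])
}

.dense_htr <- function(f, t0, peak_value, peak_time, dt = 0.005) {
  t <- seq(t0, peak_time, by = dt)
  v <- f(t)
  v0 <- v[1L]
  level <- v0 + (peak_value - v0) / 2
  dir <- sign(peak_value - v0)
  idx <- which(dir * v >= dir * level)
  idx <- idx[idx > 1L]
  if (length(idx) == 0L) return(NA_real_)
  j <- idx[1L]
  frac <- (level - v[j - 1L]) / (v[j] - v[j - 1L])
  t[j - 1L] + frac * dt - t0
}

.with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Ground-truth parameters for one synthetic VOT trace
#'
#' Collects the generator-controlled kinetic parameters of the three
#' measured channels. Chromophore occlusion extrema and times are on the
#' delta scale with times relative to cuff release (negative); hyperemia
#' peaks, times-to-peak and half-times to recovery are likewise
#' release-relative. TSI parameters are not set here: TSI emerges from the
#' two chromophores. Defaults are a typical climber-like subject.
#'
#' @param o2hb List: `base` (uM), `oc_slope` (uM/s, negative), `oc_min`
#'   (uM), `oc_tmin` (s, negative), `hy_max` (uM), `hy_tmax` (s), `hy_htr`
#'   (s).
#' @param hhb List: `base`, `oc_slope` (positive), `oc_max`, `oc_tmax`,
#'   `hy_min` (negative), `hy_tmin`, `hy_htr`.
#' @param bfi List: `base` (cm^2/s), `oc_rbf_min` (% of baseline),
#'   `hy_rbf_max` (%), `hy_rbf_tmax` (s), `hy_rbf_htr` (s).
#' @param cardiac List: `freq` (Hz, at least 1.1 so the component sits in
#'   the filter stopband), `amp_nirs` (uM), `amp_bfi_frac` (fraction of the
#'   BFI baseline).
#' @param noise_sd List of white-noise SDs: `o2hb`, `hhb` (uM) and
#'   `bfi_frac` (fraction of the BFI baseline); `NULL` sets each to 5% of
#'   the channel's dynamic range.
#' @param seed Integer seed for the trace's noise (NA: use the current RNG
#'   stream).
#' @param subject_id,group Metadata passed to the recording.
#' @return List of class `vot_ground_truth`.
#' @export
vot_ground_truth <- function(
    o2hb = list(base = 43.6, oc_slope = -0.1, oc_min = -6.5, oc_tmin = -22.2,
                hy_max = 16.6, hy_tmax = 14.4, hy_htr = 4.8),
    hhb = list(base = 24.9, oc_slope = 0.1, oc_max = 14.9, oc_tmax = -3.5,
               hy_min = -5.5, hy_tmin = 32, hy_htr = 7.1),
    bfi = list(base = 1.7e-9, oc_rbf_min = 12.3, hy_rbf_max = 873.7,
               hy_rbf_tmax = 13, hy_rbf_htr = 5.4),
    cardiac = list(freq = 1.2, amp_nirs = 1, amp_bfi_frac = 0.1),
    noise_sd = NULL, seed = NA_integer_,
    subject_id = "synthetic", group = "climber") {
  if (!is.null(cardiac$freq) && cardiac$freq < 1.1)
    stop("cardiac frequency must be at least 1.1 Hz (inside the filter stopband)",
         call. = FALSE)
  if (is.null(noise_sd)) {
    noise_sd <- list(
      o2hb = 0.05 * (o2hb$hy_max - o2hb$oc_min),
      hhb = 0.05 * (hhb$oc_max - hhb$hy_min),
      bfi_frac = 0.05 * (bfi$hy_rbf_max - bfi$oc_rbf_min) / 100)
  }
  if (!(bfi$oc_rbf_min > 0 && bfi$oc_rbf_min < 100))
    stop("rBF floor must lie in (0, 100)%", call. = FALSE)
  structure(list(o2hb = o2hb, hhb = hhb, bfi = bfi, cardiac = cardiac,
                 noise_sd = noise_sd, seed = seed,
                 subject_id = subject_id, group = group),
            class = "vot_ground_truth")
}

# Assemble the continuous noiseless channel models and the definitional
# ground-truth value of every extractable feature.
.build_model <- function(truth, proto) {
  ti <- proto$ba_s
  tr <- proto$ba_s + proto$oc_s
  w <- 1.5                                  # NIRS corner cap half-width (s)
  w_rbf <- 1.0

  oc_o2 <- .oc_shape(truth$o2hb$oc_slope, truth$o2hb$oc_min,
                     proto$oc_s + truth$o2hb$oc_tmin, proto$oc_s, w)
  oc_hh <- .oc_shape(truth$hhb$oc_slope, truth$hhb$oc_max,
                     proto$oc_s + truth$hhb$oc_tmax, proto$oc_s, w)
  v0_o2 <- oc_o2$f(proto$oc_s)
  v0_hh <- oc_hh$f(proto$oc_s)
  hy_o2 <- .hy_shape(v0_o2, truth$o2hb$hy_max, truth$o2hb$hy_tmax,
                     truth$o2hb$hy_htr, w, relax_to = 0)
  hy_hh <- .hy_shape(v0_hh, truth$hhb$hy_min, truth$hhb$hy_tmin,
                     truth$hhb$hy_htr, w, relax_to = 0)

  tau_occ <- 12                             # BFI collapse time constant (s)
  floor_ <- truth$bfi$oc_rbf_min
  rbf_oc <- function(u) floor_ + (100 - floor_) * exp(-u / tau_occ)
  v0_rbf <- rbf_oc(proto$oc_s)
  hy_rbf <- .hy_shape(v0_rbf, truth$bfi$hy_rbf_max, truth$bfi$hy_rbf_tmax,
                      truth$bfi$hy_rbf_htr, w_rbf, relax_to = 100)

  piece <- function(f_oc, f_hy) {
    function(t) ifelse(t < ti, 0,
                ifelse(t <= tr, f_oc(pmax(t - ti, 0)), f_hy(t - tr)))
  }
  d_o2 <- piece(oc_o2$f, hy_o2$f)
  d_hh <- piece(oc_hh$f, hy_hh$f)
  rbf <- function(t) ifelse(t < ti, 100,
                     ifelse(t <= tr, rbf_oc(pmax(t - ti, 0)), hy_rbf$f(t - tr)))
  tsi <- function(t) {
    o <- truth$o2hb$base + d_o2(t)
    tot <- o + truth$hhb$base + d_hh(t)
    ifelse(tot > 0, 100 * o / tot, NA_real_)
  }

  ba_tsi <- 100 * truth$o2hb$base / (truth$o2hb$base + truth$hhb$base)
  d_tsi <- function(t) tsi(t) - ba_tsi

  # definitional feature values of the continuous noiseless trace
  tsi_oc_ext <- .dense_extremum(d_tsi, ti, tr, "min")
  tsi_hy_ext <- .dense_extremum(d_tsi, tr, tr + proto$hy_s, "max")
  tsi_htr <- .dense_htr(d_tsi, tr, tsi_hy_ext$value, tsi_hy_ext$time)

  # The release-to-peak RBF slope is defined on the 1 Hz analysis stream, so
  # its ground truth lives on the same grid: 1-s bin means of the continuous
  # model, peak bin located on those means, OLS over the bins up to the peak
  tg <- seq(tr, tr + proto$hy_s - 0.005, by = 0.01)
  bin_id <- floor(tg)
  bin_mean <- tapply(rbf(tg), bin_id, mean)
  centres <- as.numeric(names(bin_mean)) + 0.5
  keep <- centres >= tr
  bin_mean <- bin_mean[keep]; centres <- centres[keep]
  kmax <- which.max(bin_mean)
  rbf_slope <- {
    sel <- seq_len(kmax)
    tc <- centres[sel] - mean(centres[sel])
    vv <- as.numeric(bin_mean[sel])
    sum(tc * (vv - mean(vv))) / sum(tc * tc)
  }
  rbf_htr <- {
    v0 <- bin_mean[[1L]]
    level <- v0 + (bin_mean[[kmax]] - v0) / 2
    j <- which(bin_mean >= level)[1L]
    if (is.na(j) || j == 1L) centres[1L] - tr else {
      frac <- (level - bin_mean[[j - 1L]]) / (bin_mean[[j]] - bin_mean[[j - 1L]])
      centres[j - 1L] + frac - tr
    }
  }

  features <- c(
    ba_o2hb = truth$o2hb$base, ba_hhb = truth$hhb$base, ba_tsi = ba_tsi,
    ba_bfi = truth$bfi$base,
    oc_d_o2hb_slope = truth$o2hb$oc_slope, oc_d_hhb_slope = truth$hhb$oc_slope,
    oc_d_tsi_slope = .dense_slope(d_tsi, ti, ti + 20),
    oc_d_o2hb_min = truth$o2hb$oc_min, oc_d_hhb_max = truth$hhb$oc_max,
    oc_d_tsi_min = tsi_oc_ext$value,
    oc_rbf_min = mean(rbf_oc(seq(proto$oc_s - 10, proto$oc_s, by = 0.01))),
    oc_d_o2hb_tmin = truth$o2hb$oc_tmin, oc_d_hhb_tmax = truth$hhb$oc_tmax,
    oc_d_tsi_tmin = tsi_oc_ext$time - tr,
    hy_d_o2hb_max = truth$o2hb$hy_max, hy_d_hhb_min = truth$hhb$hy_min,
    hy_d_tsi_max = tsi_hy_ext$value, hy_rbf_max = truth$bfi$hy_rbf_max,
    hy_d_o2hb_tmax = truth$o2hb$hy_tmax, hy_d_hhb_tmin = truth$hhb$hy_tmin,
    hy_d_tsi_tmax = tsi_hy_ext$time - tr, hy_rbf_tmax = truth$bfi$hy_rbf_tmax,
    hy_d_o2hb_slope = .dense_slope(function(u) hy_o2$f(u), 0, 10),
    hy_d_hhb_slope = .dense_slope(function(u) hy_hh$f(u), 0, 10),
    hy_d_tsi_slope = .dense_slope(d_tsi, tr, tr + 10),
    hy_rbf_slope = rbf_slope,
    hy_d_o2hb_htr = hy_o2$htr, hy_d_hhb_htr = hy_hh$htr,
    hy_d_tsi_htr = tsi_htr, hy_rbf_htr = rbf_htr)

  list(d_o2 = d_o2, d_hh = d_hh, rbf = rbf,
       features = features,
       linear_fallback = c(o2hb = hy_o2$linear, hhb = hy_hh$linear,
                           rbf = hy_rbf$linear))
}

#' Simulate one VOT recording with known ground truth
#'
#' Samples the continuous noiseless channel model (linear chromophore drift
#' during occlusion reaching its extremum exactly, saturating-exponential
#' hyperemic rise realizing the requested peak, time-to-peak and half-time
#' to recovery, BFI collapse to the rBF floor; TSI emerges from the
#' chromophores) at the protocol rates, adding a cardiac-frequency sinusoid
#' and white noise per channel. The returned ground truth carries the
#' definitional value of all 30 extractable features of the noiseless trace,
#' so extraction accuracy can be checked feature by feature.
#'
#' @param truth A [vot_ground_truth()].
#' @param protocol A [vot_protocol()].
#' @return List with `recording` (a [vot_recording()]) and `truth` (the
#'   input, with a `features` element and `linear_fallback` flags added).
#' @export
simulate_trace <- function(truth, protocol = vot_protocol()) {
  stopifnot(inherits(truth, "vot_ground_truth"))
  proto <- protocol
  model <- .build_model(truth, proto)
  total <- proto$ba_s + proto$oc_s + proto$hy_s
  ti <- proto$ba_s
  tr <- proto$ba_s + proto$oc_s

  t_nirs <- (seq_len(round(total * proto$fs_nirs)) - 1L) / proto$fs_nirs
  t_dcs <- (seq_len(floor(total * proto$fs_dcs)) - 1L) / proto$fs_dcs
  card <- truth$cardiac

  streams <- .with_seed(truth$seed, {
    carrier_n <- sin(2 * pi * card$freq * t_nirs)
    o2 <- truth$o2hb$base + model$d_o2(t_nirs) + card$amp_nirs * carrier_n +
      stats::rnorm(length(t_nirs), 0, truth$noise_sd$o2hb)
    hh <- truth$hhb$base + model$d_hh(t_nirs) - 0.5 * card$amp_nirs * carrier_n +
      stats::rnorm(length(t_nirs), 0, truth$noise_sd$hhb)
    bfi <- truth$bfi$base * (model$rbf(t_dcs) / 100 +
      card$amp_bfi_frac * sin(2 * pi * card$freq * t_dcs) +
      stats::rnorm(length(t_dcs), 0, truth$noise_sd$bfi_frac))
    list(channel_stream("O2HB", o2, fs = proto$fs_nirs),
         channel_stream("HHB", hh, fs = proto$fs_nirs),
         channel_stream("BFI", bfi, fs = proto$fs_dcs))
  })

  rec <- vot_recording(
    streams,
    cuff_events(t_inflate = ti, t_release = tr, end_time = total,
                t_contract = ti - proto$contraction_s),
    subject_meta(truth$subject_id, truth$group))
  truth$features <- model$features
  truth$linear_fallback <- model$linear_fallback
  list(recording = rec, truth = truth)
}

#' Reference group parameters for cohort simulation
#'
#' Generator parameter means and SDs for the two study groups (climbers
#' n = 17, non-climbers n = 15), taken from the published group summary
#' statistics of the chromophore and blood-flow kinetics. Only the
#' generator-controlled parameters appear; TSI parameters are emergent.
#'
#' @param group `"climber"` or `"nonclimber"`.
#' @return List of class `group_params`: per-channel `(mean, sd)` pairs
#'   plus cohort size `n`.
#' @export
reference_group_params <- function(group = c("climber", "nonclimber")) {
  group <- match.arg(group)
  p <- if (group == "climber") list(
    n = 17,
    o2hb = list(base = c(43.6, 10.7), oc_slope = c(-0.1, 0.1),
                oc_min = c(-6.5, 6.4), oc_tmin = c(-22.2, 43.6),
                hy_max = c(16.6, 3.9), hy_tmax = c(14.4, 4.2),
                hy_htr = c(4.8, 1.8)),
    hhb = list(base = c(24.9, 4), oc_slope = c(0.1, 0),
               oc_max = c(14.9, 4.1), oc_tmax = c(-3.5, 12.8),
               hy_min = c(-5.5, 2.4), hy_tmin = c(32, 7.8),
               hy_htr = c(7.1, 3.1)),
    bfi = list(base = c(1.7e-9, 9.12e-10), oc_rbf_min = c(12.3, 7.1),
               hy_rbf_max = c(873.7, 440.3), hy_rbf_tmax = c(13, 6.5),
               hy_rbf_htr = c(5.4, 4.3))
  ) else list(
    n = 15,
    o2hb = list(base = c(39.1, 11.7), oc_slope = c(-0.1, 0.1),
                oc_min = c(-8.6, 5.4), oc_tmin = c(-3.9, 7.8),
                hy_max = c(11.3, 4.4), hy_tmax = c(16.3, 4.6),
                hy_htr = c(5.3, 1.9)),
    hhb = list(base = c(19.1, 4.1), oc_slope = c(0.1, 0),
               oc_max = c(15, 6), oc_tmax = c(-2.8, 8.8),
               hy_min = c(-3.3, 1.9), hy_tmin = c(33.9, 9.1),
               hy_htr = c(7.6, 2.7)),
    bfi = list(base = c(1.4e-9, 4.25e-10), oc_rbf_min = c(12, 4.1),
               hy_rbf_max = c(712.4, 151), hy_rbf_tmax = c(15.6, 5.9),
               hy_rbf_htr = c(4, 2.1))
  )
  structure(c(p, list(group = group)), class = "group_params")
}

# Draw one subject's kinetic parameters from independent normals, jointly
# resampled until the piecewise model is well posed (truncated-normal
# draws; keeps cohort size fixed).
.draw_subject_params <- function(gp, proto, max_tries = 5000) {
  w <- 1.5; w_rbf <- 1.0
  rn <- function(ms) stats::rnorm(1, ms[1], ms[2])
  valid_oc <- function(s, e, te_rel) {
    te <- proto$oc_s + te_rel
    if (!(te - w > 20.5 && te + w < proto$oc_s - 0.5)) return(FALSE)
    if (!(sign(s) != 0 && sign(e) == sign(s))) return(FALSE)
    if (!(abs(e) > 21 * abs(s))) return(FALSE)
    # recovery drift must not retrace more than half the extremum
    a <- (abs(e) - 20 * abs(s)) / (te - 20)
    a * (-te_rel) <= 0.5 * abs(e)
  }
  valid_hy <- function(peak_h, tp, htr, wc) {
    tp > wc + 1.5 && tp + wc < proto$hy_s - 5 && peak_h > 0.3 &&
      htr > 0.2 && htr < 0.98 * (tp - wc / 2) / 2
  }
  # the quadratic peak cap lowers the attainable peak by at most
  # h0*w/(2*(tp-w)); the capped peak must stay above the relaxation level
  feasible_peak <- function(v0, peak, tp, relax_to, wc) {
    dir <- sign(peak - v0)
    h0 <- abs(peak - v0)
    dir * peak - h0 * wc / (2 * (tp - wc)) > dir * relax_to + 0.02 * h0
  }
  for (i in seq_len(max_tries)) {
    o2 <- lapply(gp$o2hb, rn); hh <- lapply(gp$hhb, rn); bf <- lapply(gp$bfi, rn)
    ok <- o2$base > 5 && hh$base > 2 &&
      o2$oc_slope < -0.005 && hh$oc_slope > 0.005 &&
      valid_oc(o2$oc_slope, o2$oc_min, o2$oc_tmin) &&
      valid_oc(hh$oc_slope, hh$oc_max, hh$oc_tmax) &&
      o2$hy_max > 1 && valid_hy(o2$hy_max, o2$hy_tmax, o2$hy_htr, w) &&
      hh$hy_min < -0.3 && valid_hy(-hh$hy_min, hh$hy_tmin, hh$hy_htr, w) &&
      bf$base > 2e-10 && bf$oc_rbf_min > 1 && bf$oc_rbf_min < 50 &&
      bf$hy_rbf_max > 150 &&
      valid_hy(bf$hy_rbf_max - 100, bf$hy_rbf_tmax, bf$hy_rbf_htr, w_rbf)
    if (ok) {
      # exact release values, then capped-peak feasibility per channel
      v0_o2 <- .oc_shape(o2$oc_slope, o2$oc_min, proto$oc_s + o2$oc_tmin,
                         proto$oc_s, w)$f(proto$oc_s)
      v0_hh <- .oc_shape(hh$oc_slope, hh$oc_max, proto$oc_s + hh$oc_tmax,
                         proto$oc_s, w)$f(proto$oc_s)
      v0_bf <- bf$oc_rbf_min + (100 - bf$oc_rbf_min) * exp(-proto$oc_s / 12)
      ok <- feasible_peak(v0_o2, o2$hy_max, o2$hy_tmax, 0, w) &&
        feasible_peak(v0_hh, hh$hy_min, hh$hy_tmin, 0, w) &&
        feasible_peak(v0_bf, bf$hy_rbf_max, bf$hy_rbf_tmax, 100, w_rbf)
    }
    if (ok) return(list(o2hb = o2, hhb = hh, bfi = bf))
  }
  stop("could not draw valid subject parameters in ", max_tries, " tries",
       call. = FALSE)
}

#' Simulate a two-group VOT cohort with per-subject ground truth
#'
#' Draws each subject's kinetic parameters from independent normals with
#' the group's means and SDs (truncated to model validity by joint
#' resampling, so cohort sizes stay fixed), then builds the traces with
#' [simulate_trace()]. All randomness flows from `seed`, so a fixed seed
#' reproduces the cohort exactly.
#'
#' @param climber,nonclimber [reference_group_params()]-shaped parameter
#'   sets (defaults: the published group summaries).
#' @param seed Integer seed.
#' @param protocol A [vot_protocol()].
#' @param cardiac,noise_sd Passed to every subject's [vot_ground_truth()]
#'   (`noise_sd = NULL`: 5% of each subject's dynamic range).
#' @return List with `recordings` (list of [vot_recording()]s) and `truth`
#'   (data frame: `subject_id`, `group`, one column per ground-truth
#'   feature).
#' @export
simulate_cohort <- function(climber = reference_group_params("climber"),
                            nonclimber = reference_group_params("nonclimber"),
                            seed = 1, protocol = vot_protocol(),
                            cardiac = list(freq = 1.2, amp_nirs = 1,
                                           amp_bfi_frac = 0.1),
                            noise_sd = NULL) {
  .with_seed(seed, {
    recordings <- list()
    truth_rows <- list()
    for (gp in list(climber, nonclimber)) {
      for (i in seq_len(gp$n)) {
        pars <- .draw_subject_params(gp, protocol)
        id <- sprintf("%s%02d", substr(gp$group, 1, 1), i)
        gt <- vot_ground_truth(o2hb = pars$o2hb, hhb = pars$hhb,
                               bfi = pars$bfi, cardiac = cardiac,
                               noise_sd = noise_sd, seed = NA_integer_,
                               subject_id = id, group = gp$group)
        sim <- simulate_trace(gt, protocol)
        recordings[[id]] <- sim$recording
        truth_rows[[id]] <- cbind(
          data.frame(subject_id = id, group = gp$group,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(sim$truth$features)))
      }
    }
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    list(recordings = recordings, truth = truth)
  })
}
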