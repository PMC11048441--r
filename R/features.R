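#' Names of the per-subject VOT parameters
#'
#' The full parameter catalogue extracted from one vascular occlusion test:
#' 4 baseline means, 10 occlusion-phase parameters, and 16 hyperemia-phase
#' parameters (peak, time-to-peak, initial slope and half-time to recovery
#' for each of the three NIRS delta signals and the relative blood flow).
#' Time-to-peak values are reported relative to cuff release, so occlusion
#' times are non-positive and hyperemia times non-negative.
#'
#' @format Character vector of 30 feature names.
#' @export
vot_feature_names <- c(
  "ba_o2hb", "ba_hhb", "ba_tsi", "ba_bfi",
  "oc_d_o2hb_slope", "oc_d_hhb_slope", "oc_d_tsi_slope",
  "oc_d_o2hb_min", "oc_d_hhb_max", "oc_d_tsi_min", "oc_rbf_min",
  "oc_d_o2hb_tmin", "oc_d_hhb_tmax", "oc_d_tsi_tmin",
  "hy_d_o2hb_max", "hy_d_hhb_min", "hy_d_tsi_max", "hy_rbf_max",
  "hy_d_o2hb_tmax", "hy_d_hhb_tmin", "hy_d_tsi_tmax", "hy_rbf_tmax",
  "hy_d_o2hb_slope", "hy_d_hhb_slope", "hy_d_tsi_slope", "hy_rbf_slope",
  "hy_d_o2hb_htr", "hy_d_hhb_htr", "hy_d_tsi_htr", "hy_rbf_htr"
)

#' Segment a recording into baseline, occlusion and hyperemia windows
#'
#' The occlusion window runs from cuff inflation to release and the hyperemia
#' window for `hy_window` seconds after release. The baseline mean is taken
#' over a `ba_window`-second window ending at inflation — or, when a light
#' contraction is annotated shortly before inflation, ending `ba_guard`
#' seconds earlier so the contraction transient stays out of the baseline.
#'
#' @param events A [cuff_events()].
#' @param ba_window Baseline window length (s), default 60.
#' @param hy_window Hyperemia window length (s), default 180.
#' @param ba_guard Gap between baseline end and inflation when a contraction
#'   is annotated (s), default 15.
#' @param rec_start Earliest recorded time (s), default 0.
#' @return An object of class `phase_windows`: list of closed intervals
#'   `ba`, `oc`, `hy` (each `c(start, end)` in absolute seconds).
#' @export
segment_phases <- function(events, ba_window = 60, hy_window = 180,
                           ba_guard = 15, rec_start = 0) {
  stopifnot(inherits(events, "cuff_events"))
  ba_end <- if (is.finite(events$t_contract)) events$t_inflate - ba_guard
            else events$t_inflate
  ba <- c(ba_end - ba_window, ba_end)
  if (ba[1] < rec_start)
    stop("baseline phase too short: window would start ", rec_start - ba[1],
         " s before the recording", call. = FALSE)
  hy <- c(events$t_release, events$t_release + hy_window)
  if (hy[2] > events$end_time)
    stop("hyperemia phase too short: ", hy_window,
         " s requested but recording ends ", events$end_time - events$t_release,
         " s after release", call. = FALSE)
  structure(list(ba = ba, oc = c(events$t_inflate, events$t_release), hy = hy),
            class = "phase_windows")
}

#' @export
print.phase_windows <- function(x, ...) {
  cat(sprintf("<phase_windows> BA [%.1f, %.1f]  OC [%.1f, %.1f]  HY [%.1f, %.1f] s\n",
              x$ba[1], x$ba[2], x$oc[1], x$oc[2], x$hy[1], x$hy[2]))
  invisible(x)
}

#' Baseline means of the measured channels
#'
#' Arithmetic mean of each channel over the baseline window, ignoring
#' missing samples; fails if more than 20% of a channel's baseline samples
#' are missing.
#'
#' @param rec A (preprocessed) [vot_recording()].
#' @param windows A [segment_phases()] result.
#' @return List with `ba_o2hb`, `ba_hhb`, `ba_tsi`, `ba_bfi` (absent
#'   channels are `NA`), class `baseline_values`.
#' @export
compute_baseline <- function(rec, windows) {
  one <- function(ch) {
    s <- rec$streams[[ch]]
    if (is.null(s)) return(NA_real_)
    w <- stream_window(s, windows$ba)
    if (length(w$values) == 0L)
      stop("baseline window not covered by ", ch, call. = FALSE)
    if (mean(is.na(w$values)) > 0.2)
      stop("more than 20% of baseline samples missing in ", ch, call. = FALSE)
    mean(w$values, na.rm = TRUE)
  }
  structure(list(ba_o2hb = one("O2HB"), ba_hhb = one("HHB"),
                 ba_tsi = one("TSI"), ba_bfi = one("BFI")),
            class = "baseline_values")
}

#' Re-express channels relative to their baseline
#'
#' Adds the delta streams used by all occlusion/hyperemia parameters:
#' `D_O2HB`, `D_HHB`, `D_TSI` (channel minus its baseline mean) and `RBF`
#' (blood flow index as percent of the baseline mean,
#' `100 * BFI / ba_bfi`).
#'
#' @param rec A (preprocessed) [vot_recording()].
#' @param base A [compute_baseline()] result.
#' @return The recording with the derived streams appended.
#' @export
normalize_recording <- function(rec, base) {
  stopifnot(inherits(base, "baseline_values"))
  streams <- rec$streams
  delta <- function(ch, dch, ba) {
    s <- streams[[ch]]
    if (is.null(s) || !is.finite(ba)) return(NULL)
    channel_stream(dch, s$values - ba, fs = s$fs, t0 = s$t0)
  }
  add <- list(delta("O2HB", "D_O2HB", base$ba_o2hb),
              delta("HHB", "D_HHB", base$ba_hhb),
              delta("TSI", "D_TSI", base$ba_tsi))
  if (!is.null(streams$BFI)) {
    if (!is.finite(base$ba_bfi) || base$ba_bfi <= 0)
      stop("non-positive baseline flow: cannot form relative blood flow",
           call. = FALSE)
    s <- streams$BFI
    add <- c(add, list(channel_stream("RBF", 100 * s$values / base$ba_bfi,
                                      fs = s$fs, t0 = s$t0)))
  }
  vot_recording(c(streams, Filter(Negate(is.null), add)), rec$events, rec$meta)
}

#' Ordinary-least-squares slope over a time window
#'
#' @param stream A [channel_stream()].
#' @param window Closed interval `c(start, end)` in absolute seconds.
#' @return Slope in stream units per second.
#' @export
fit_window_slope <- function(stream, window) {
  w <- stream_window(stream, window)
  ok <- !is.na(w$values)
  if (sum(ok) < 5L)
    stop("window underpopulated: ", sum(ok), " usable samples in [",
         window[1], ", ", window[2], "] of ", stream$name, call. = FALSE)
  t <- w$t[ok] - mean(w$t[ok])
  v <- w$values[ok]
  sum(t * (v - mean(v))) / sum(t * t)
}

#' Extremum of a stream in a window, with release-relative timing
#'
#' Finds the minimum or maximum sample in the closed window; ties are broken
#' to the earliest occurrence. The time is reported relative to `t_ref`
#' (conventionally the cuff release, which makes occlusion extrema times
#' non-positive and hyperemia times non-negative).
#'
#' @param stream A [channel_stream()].
#' @param window Closed interval `c(start, end)` in absolute seconds.
#' @param mode `"min"` or `"max"`.
#' @param t_ref Reference time subtracted from the extremum's absolute time.
#' @return List with `value` and `time_rel` (s).
#' @export
find_extremum <- function(stream, window, mode = c("min", "max"), t_ref = 0) {
  mode <- match.arg(mode)
  w <- stream_window(stream, window)
  if (length(w$values) == 0L || all(is.na(w$values)))
    stop("no usable samples in window [", window[1], ", ", window[2], "] of ",
         stream$name, call. = FALSE)
  k <- if (mode == "min") which.min(w$values) else which.max(w$values)
  list(value = w$values[k], time_rel = w$t[k] - t_ref)
}

#' Relative-blood-flow floor during occlusion
#'
#' The occlusion minimum of relative blood flow is defined as the mean RBF
#' over the last `tail_s` seconds before cuff release (rather than the
#' noisier single lowest sample).
#'
#' @param rbf The `RBF` [channel_stream()].
#' @param t_release Cuff release time (s).
#' @param tail_s Averaging window length (s), default 10.
#' @return Mean RBF in percent of baseline.
#' @export
oc_rbf_min <- function(rbf, t_release, tail_s = 10) {
  w <- stream_window(rbf, c(t_release - tail_s, t_release))
  if (length(w$values) == 0L || all(is.na(w$values)))
    stop("pre-release window [", t_release - tail_s, ", ", t_release,
         "] not covered by RBF", call. = FALSE)
  mean(w$values, na.rm = TRUE)
}

#' Half-time to recovery of the hyperemic response
#'
#' Time elapsed from cuff release until the signal first reaches half the
#' height of its hyperemic response, where height is the peak value minus
#' the value at release (the first non-missing sample at or after release).
#' The crossing is located by linear interpolation between the bracketing
#' samples and is always at or before the time of the peak. Works for
#' rising responses (oxyhemoglobin, TSI, relative blood flow) and falling
#' ones (deoxyhemoglobin) alike.
#'
#' @param stream A [channel_stream()].
#' @param t_release Cuff release time (s).
#' @param peak_value,peak_time_rel Peak of the same stream over the
#'   hyperemia window, as returned by [find_extremum()] with
#'   `t_ref = t_release`.
#' @return Half-time to recovery in seconds (relative to release).
#' @export
compute_htr <- function(stream, t_release, peak_value, peak_time_rel) {
  w <- stream_window(stream, c(t_release, t_release + peak_time_rel))
  ok <- which(!is.na(w$values))
  if (length(ok) == 0L)
    stop("no usable samples between release and peak in ", stream$name,
         call. = FALSE)
  i0 <- ok[1L]
  v0 <- w$values[i0]
  height <- peak_value - v0
  if (abs(height) <= 1e-8 * max(abs(peak_value), abs(v0), 1))
    stop("half level not reached: flat response in ", stream$name, call. = FALSE)
  level <- v0 + height / 2
  dir <- sign(height)
  v <- w$values * dir       # reduce to the rising case
  lv <- level * dir
  for (j in seq(i0, length(v))) {
    if (is.na(v[j])) next
    if (v[j] >= lv) {
      if (j == i0) return(w$t[j] - t_release)
      # bracketing sample: last non-missing before j
      prev <- max(ok[ok < j])
      frac <- (lv - v[prev]) / (v[j] - v[prev])
      return(w$t[prev] + frac * (w$t[j] - w$t[prev]) - t_release)
    }
  }
  stop("half level not reached before the peak in ", stream$name, call. = FALSE)
}

#' Hyperemic slope of relative blood flow
#'
#' Ordinary-least-squares slope of RBF from cuff release to its hyperemic
#' peak.
#'
#' @param rbf The `RBF` [channel_stream()].
#' @param t_release Cuff release time (s).
#' @param peak_time_rel Time of the RBF peak relative to release (s).
#' @return Slope in percent of baseline per second.
#' @export
hy_rbf_slope <- function(rbf, t_release, peak_time_rel) {
  w <- stream_window(rbf, c(t_release, t_release + peak_time_rel))
  ok <- !is.na(w$values)
  if (sum(ok) < 3L)
    stop("window underpopulated: ", sum(ok),
         " RBF samples between release and peak", call. = FALSE)
  t <- w$t[ok] - mean(w$t[ok])
  v <- w$values[ok]
  sum(t * (v - mean(v))) / sum(t * t)
}

#' Extract the full VOT parameter set from one recording
#'
#' Runs baseline estimation, normalisation and every parameter definition on
#' a preprocessed recording: 20-s occlusion slopes from inflation, occlusion
#' extrema over the whole occlusion, the pre-release RBF floor, hyperemia
#' extrema over the whole hyperemia window, 10-s post-release NIRS slopes,
#' the release-to-peak RBF slope, and half-times to recovery. All times are
#' relative to cuff release. Parameters whose source channel is absent come
#' out `NA`; a degenerate hyperemia (no response height, so no half-level
#' crossing) sets the affected half-time to `NA` and records a finding
#' rather than failing the subject.
#'
#' @param rec A [preprocess_recording()] output (or any recording already
#'   carrying analysis-ready streams).
#' @param ba_window,hy_window,ba_guard Passed to [segment_phases()].
#' @param oc_slope_s Occlusion slope window length (s), default 20.
#' @param hy_slope_s Post-release NIRS slope window length (s), default 10.
#' @param rbf_tail_s Pre-release RBF averaging window (s), default 10.
#' @return Named list of the [vot_feature_names] values with attributes
#'   `subject_id`, `group` and `findings`; class `vot_features`.
#' @export
extract_features <- function(rec, ba_window = 60, hy_window = 180,
                             ba_guard = 15, oc_slope_s = 20, hy_slope_s = 10,
                             rbf_tail_s = 10) {
  stopifnot(inherits(rec, "vot_recording"))
  ev <- rec$events
  windows <- segment_phases(ev, ba_window, hy_window, ba_guard)
  base <- compute_baseline(rec, windows)
  rec <- normalize_recording(rec, base)
  streams <- rec$streams
  findings <- character(0)

  f <- stats::setNames(as.list(rep(NA_real_, length(vot_feature_names))),
                       vot_feature_names)
  f[c("ba_o2hb", "ba_hhb", "ba_tsi", "ba_bfi")] <- base

  oc_slope_w <- c(ev$t_inflate, ev$t_inflate + oc_slope_s)
  hy_slope_w <- c(ev$t_release, ev$t_release + hy_slope_s)

  nirs <- list(
    list(ch = "D_O2HB", tag = "d_o2hb", oc_mode = "min", hy_mode = "max"),
    list(ch = "D_HHB",  tag = "d_hhb",  oc_mode = "max", hy_mode = "min"),
    list(ch = "D_TSI",  tag = "d_tsi",  oc_mode = "min", hy_mode = "max"))
  for (cfg in nirs) {
    s <- streams[[cfg$ch]]
    if (is.null(s)) next
    f[[paste0("oc_", cfg$tag, "_slope")]] <- fit_window_slope(s, oc_slope_w)
    oc_ext <- find_extremum(s, windows$oc, cfg$oc_mode, t_ref = ev$t_release)
    f[[paste0("oc_", cfg$tag, "_", substr(cfg$oc_mode, 1, 3))]] <- oc_ext$value
    f[[paste0("oc_", cfg$tag, "_t", substr(cfg$oc_mode, 1, 3))]] <- oc_ext$time_rel
    hy_ext <- find_extremum(s, windows$hy, cfg$hy_mode, t_ref = ev$t_release)
    f[[paste0("hy_", cfg$tag, "_", substr(cfg$hy_mode, 1, 3))]] <- hy_ext$value
    f[[paste0("hy_", cfg$tag, "_t", substr(cfg$hy_mode, 1, 3))]] <- hy_ext$time_rel
    f[[paste0("hy_", cfg$tag, "_slope")]] <- fit_window_slope(s, hy_slope_w)
    htr <- tryCatch(
      compute_htr(s, ev$t_release, hy_ext$value, hy_ext$time_rel),
      error = function(e) {
        findings <<- c(findings, paste0(cfg$ch, ": ", conditionMessage(e)))
        NA_real_
      })
    f[[paste0("hy_", cfg$tag, "_htr")]] <- htr
  }

  rbf <- streams$RBF
  if (!is.null(rbf)) {
    f$oc_rbf_min <- oc_rbf_min(rbf, ev$t_release, rbf_tail_s)
    hy_ext <- find_extremum(rbf, windows$hy, "max", t_ref = ev$t_release)
    f$hy_rbf_max <- hy_ext$value
    f$hy_rbf_tmax <- hy_ext$time_rel
    f$hy_rbf_slope <- tryCatch(
      hy_rbf_slope(rbf, ev$t_release, hy_ext$time_rel),
      error = function(e) {
        findings <<- c(findings, paste0("RBF: ", conditionMessage(e)))
        NA_real_
      })
    f$hy_rbf_htr <- tryCatch(
      compute_htr(rbf, ev$t_release, hy_ext$value, hy_ext$time_rel),
      error = function(e) {
        findings <<- c(findings, paste0("RBF: ", conditionMessage(e)))
        NA_real_
      })
  }

  structure(f, class = "vot_features",
            subject_id = rec$meta$subject_id, group = rec$meta$group,
            findings = findings)
}

#' @export
print.vot_features <- function(x, ...) {
  cat(sprintf("<vot_features> subject %s (%s)\n",
              attr(x, "subject_id"), attr(x, "group")))
  v <- unlist(x)
  print(data.frame(value = signif(v, 4), row.names = names(v)))
  fnd <- attr(x, "findings")
  if (length(fnd)) cat("findings:\n", paste0("  - ", fnd, collapse = "\n"), "\n")
  invisible(x)
}

#' Extract features for a list of recordings into a cohort table
#'
#' @param recs List of preprocessed [vot_recording()]s.
#' @param ... Passed to [extract_features()].
#' @return Data frame with `subject_id`, `group` and one column per
#'   [vot_feature_names] entry; per-subject findings are kept in the
#'   `findings` attribute.
#' @export
extract_cohort <- function(recs, ...) {
  rows <- lapply(recs, function(r) {
    fs <- extract_features(r, ...)
    cbind(data.frame(subject_id = attr(fs, "subject_id"),
                     group = attr(fs, "group"), stringsAsFactors = FALSE),
          as.data.frame(lapply(fs, as.numeric)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
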