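#' Low-pass filter specification for cardiac-band removal
#'
#' The analysis removes heart-rate content from every channel with a
#' zero-phase FIR low-pass before any feature is computed. The default
#' contract — unity gain (within 0.1%) below 1 Hz, at least 60 dB attenuation
#' above 1.3 Hz — brackets resting cardiac frequencies (about 1.1–1.7 Hz)
#' while leaving the slow occlusion/hyperemia kinetics untouched.
#'
#' @param f_pass Passband edge (Hz), default 1.0.
#' @param f_stop Stopband edge (Hz), default 1.3.
#' @param stop_atten Minimum stopband attenuation (dB), default 60.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(f_pass = 1.0, f_stop = 1.3, stop_atten = 60) {
  if (!(f_pass > 0 && f_stop > f_pass))
    stop("filter spec requires 0 < f_pass < f_stop", call. = FALSE)
  if (stop_atten <= 0) stop("stop_atten must be positive", call. = FALSE)
  structure(list(f_pass = f_pass, f_stop = f_stop, stop_atten = stop_atten,
                 phase = "zero"),
            class = "filter_spec")
}

# Kaiser-window linear-phase FIR realising the passband/stopband contract
# at sampling rate fs.
# Even order (odd tap count) so the group delay is an integer sample count;
# taps normalised to exact unit DC gain. Designs are cached per (fs, spec).
.design_cache <- new.env(parent = emptyenv())

.design_lowpass <- function(fs, spec) {
  key <- sprintf("%.9g|%.9g|%.9g|%.9g", fs, spec$f_pass, spec$f_stop, spec$stop_atten)
  hit <- .design_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (!(spec$f_stop < fs / 2))
    stop("sampling rate ", fs, " Hz too low for stopband edge ", spec$f_stop,
         " Hz", call. = FALSE)
  dev <- 10^(-spec$stop_atten / 20)
  ko <- signal::kaiserord(c(spec$f_pass, spec$f_stop), c(1, 0),
                          dev = c(dev, dev), Fs = fs)
  n <- ko$n + ko$n %% 2L
  h <- signal::fir1(n, ko$Wc, type = "low", window = signal::kaiser(n + 1, ko$beta))
  h <- h / sum(h)
  .design_cache[[key]] <- h
  h
}

#' Apply the cardiac-removal low-pass to one channel
#'
#' Zero-phase filtering: a symmetric (linear-phase) FIR is applied by FFT
#' convolution with the group delay compensated exactly, so peaks and
#' crossings do not shift. Edges are odd-reflection padded by one filter
#' length and trimmed afterwards, which keeps ramps and plateaus free of
#' startup transients. Interior missing samples are linearly interpolated
#' before filtering and restored to `NA` afterwards.
#'
#' @param stream A [channel_stream()].
#' @param spec A [filter_spec()].
#' @return A filtered [channel_stream()] with unchanged `fs`, `t0`, length.
#' @export
apply_lowpass <- function(stream, spec = filter_spec()) {
  h <- .design_lowpass(stream$fs, spec)
  L <- length(h)
  g <- (L - 1L) %/% 2L
  x <- stream$values
  n <- length(x)
  if (n <= L)
    stop("channel ", stream$name, ": too short to filter (", n,
         " samples, filter length ", L, ")", call. = FALSE)
  na_idx <- which(is.na(x))
  if (length(na_idx)) {
    obs <- which(!is.na(x))
    if (length(obs) < 2L)
      stop("channel ", stream$name, ": too few observed samples to filter",
           call. = FALSE)
    x <- stats::approx(obs, x[obs], xout = seq_len(n), rule = 2)$y
  }
  pad_l <- 2 * x[1L] - x[(L + 1L):2L]
  pad_r <- 2 * x[n] - x[(n - 1L):(n - L)]
  xp <- c(pad_l, x, pad_r)
  y_full <- stats::convolve(xp, rev(h), type = "open")
  y <- y_full[(L + g + 1L):(L + g + n)]
  if (length(na_idx)) y[na_idx] <- NA_real_
  out <- stream
  out$values <- y
  out
}

#' Average a stream into non-overlapping time bins
#'
#' Reduces a high-rate stream (typically the DCS blood flow index) to a lower
#' analysis rate by averaging over contiguous bins of width `1/out_fs`
#' aligned to the stream start. Each output sample is the mean of the
#' non-missing samples in its bin (an all-missing bin yields `NA`) and is
#' stamped at the bin centre. A trailing bin not fully covered by the input
#' is dropped.
#'
#' @param stream A [channel_stream()].
#' @param out_fs Output rate in Hz; must be below `stream$fs`.
#' @return A [channel_stream()] at `out_fs` with `t0` at the first bin centre.
#' @export
bin_average <- function(stream, out_fs = 1) {
  if (!(out_fs > 0 && out_fs < stream$fs))
    stop("bin_average: out_fs must be positive and below the input rate",
         call. = FALSE)
  n <- length(stream$values)
  # bin of sample k (0-based times k/fs): floor(t * out_fs), with an epsilon
  # so samples landing exactly on a bin edge go to the later bin consistently
  bin <- floor(((seq_len(n) - 1L) / stream$fs) * out_fs + 1e-9)
  n_bins <- floor(n / stream$fs * out_fs + 1e-9)
  if (n_bins < 1L) stop("bin_average: stream shorter than one bin", call. = FALSE)
  keep <- bin < n_bins
  sums <- tapply(stream$values[keep], bin[keep],
                 function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  vals <- as.numeric(sums[as.character(0:(n_bins - 1L))])
  out <- stream
  out$fs <- out_fs
  out$t0 <- stream$t0 + 0.5 / out_fs
  out$values <- vals
  out
}

#' Tissue saturation index from the chromophore channels
#'
#' TSI is the oxygenated fraction of total hemoglobin, in percent:
#' `100 * O2Hb / (O2Hb + HHb)`, computed sample-wise. Samples where the total
#' is non-positive (physically meaningless on the arbitrary concentration
#' scale) come out missing.
#'
#' @param o2hb,hhb [channel_stream()]s on identical time bases (same `fs`,
#'   `t0`, length), both in the same concentration unit.
#' @return A `TSI` [channel_stream()] in percent.
#' @export
compute_tsi <- function(o2hb, hhb) {
  if (abs(o2hb$fs - hhb$fs) > 1e-9 || abs(o2hb$t0 - hhb$t0) > 1e-9 ||
      length(o2hb$values) != length(hhb$values))
    stop("compute_tsi: O2Hb and HHb time bases differ", call. = FALSE)
  tot <- o2hb$values + hhb$values
  tsi <- ifelse(!is.na(tot) & tot > 0, 100 * o2hb$values / tot, NA_real_)
  channel_stream("TSI", tsi, fs = o2hb$fs, t0 = o2hb$t0)
}

#' Preprocess a recording to analysis-ready streams
#'
#' Runs the standard conditioning chain: the NIRS chromophores are low-pass
#' filtered at their native rate and TSI is derived from them; the BFI stream
#' is low-pass filtered and then bin-averaged to `dcs_out_fs` (default 1 Hz)
#' to tame shot noise and residual pulsatility. Channels absent from the
#' input are simply skipped, so NIRS-only or DCS-only recordings pass
#' through without error.
#'
#' @param rec A [vot_recording()].
#' @param spec A [filter_spec()].
#' @param dcs_out_fs Analysis rate for the averaged BFI stream (Hz).
#' @param tsi_stage Compute TSI from filtered chromophores (`"post_filter"`,
#'   default) or from the raw ones before filtering (`"pre_filter"`, in which
#'   case the TSI stream itself is then filtered).
#' @return A [vot_recording()] carrying the processed streams.
#' @export
preprocess_recording <- function(rec, spec = filter_spec(), dcs_out_fs = 1,
                                 tsi_stage = c("post_filter", "pre_filter")) {
  stopifnot(inherits(rec, "vot_recording"))
  tsi_stage <- match.arg(tsi_stage)
  out <- list()
  if (all(c("O2HB", "HHB") %in% names(rec$streams))) {
    o2 <- apply_lowpass(rec$streams$O2HB, spec)
    hh <- apply_lowpass(rec$streams$HHB, spec)
    tsi <- if (tsi_stage == "post_filter") compute_tsi(o2, hh)
           else apply_lowpass(compute_tsi(rec$streams$O2HB, rec$streams$HHB), spec)
    out <- c(out, list(o2, hh, tsi))
  }
  if ("BFI" %in% names(rec$streams)) {
    bfi <- bin_average(apply_lowpass(rec$streams$BFI, spec), dcs_out_fs)
    out <- c(out, list(bfi))
  }
  if (length(out) == 0L)
    stop("recording has neither a chromophore pair nor a BFI stream", call. = FALSE)
  vot_recording(out, rec$events, rec$meta)
}
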