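#' Uniformly sampled physiological channel
#'
#' A `channel_stream` holds one uniformly sampled signal from a VOT recording:
#' a NIRS chromophore (`O2HB`, `HHB`, in arbitrary micromolar), the tissue
#' saturation index (`TSI`, %), the DCS blood flow index (`BFI`, cm^2/s), the
#' relative blood flow (`RBF`, % of baseline), or one of the baseline-delta
#' streams derived by [normalize_recording()] (`D_O2HB`, `D_HHB`, `D_TSI`).
#' Sample k (1-based) is located at time `t0 + (k - 1) / fs` seconds.
#' Missing samples are `NA`.
#'
#' @param name Channel identifier, one of
#'   `"O2HB", "HHB", "TSI", "BFI", "RBF", "D_O2HB", "D_HHB", "D_TSI"`.
#' @param values Numeric vector of samples (`NA` = missing).
#' @param fs Sampling frequency in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param unit Unit string; defaults to the conventional unit for `name`.
#' @return An object of class `channel_stream`.
#' @examples
#' s <- channel_stream("O2HB", values = rnorm(100, 43), fs = 50)
#' stream_times(s)[1:3]
#' @export
channel_stream <- function(name, values, fs, t0 = 0, unit = NULL) {
  name <- match.arg(toupper(name), names(.channel_units))
  if (is.null(unit)) unit <- .channel_units[[name]]
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("channel ", name, ": fs must be a positive number", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("channel ", name, ": t0 must be a finite number", call. = FALSE)
  values <- as.numeric(values)
  if (any(is.infinite(values)))
    stop("channel ", name, ": non-finite sample values (use NA for missing)",
         call. = FALSE)
  structure(
    list(name = name, unit = unit, fs = fs, t0 = t0, values = values),
    class = "channel_stream"
  )
}

.channel_units <- c(
  O2HB = "uM", HHB = "uM", TSI = "%", BFI = "cm^2/s", RBF = "%baseline",
  D_O2HB = "uM", D_HHB = "uM", D_TSI = "%"
)

#' @export
print.channel_stream <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf(
    "<channel_stream> %s [%s], fs = %g Hz, n = %d (%.1f s from t = %.2f s), %d missing\n",
    x$name, x$unit, x$fs, n, n / x$fs, x$t0, sum(is.na(x$values))
  ))
  invisible(x)
}

#' Sample times of a channel stream
#'
#' @param stream A [channel_stream()].
#' @return Numeric vector of absolute sample times in seconds.
#' @export
stream_times <- function(stream) {
  stream$t0 + (seq_along(stream$values) - 1L) / stream$fs
}

#' Extract the samples of a stream falling in a closed time window
#'
#' @param stream A [channel_stream()].
#' @param window Numeric `c(start, end)` in absolute seconds, closed interval.
#' @return A list with `t` (times) and `values` for samples inside the window.
#' @export
stream_window <- function(stream, window) {
  stopifnot(length(window) == 2L, window[2] >= window[1])
  # index arithmetic rather than scanning all timestamps; tiny epsilon guards
  # against ties falling off the closed boundary through float rounding
  eps <- 1e-9
  k0 <- max(1L, as.integer(ceiling((window[1] - stream$t0) * stream$fs - eps)) + 1L)
  k1 <- min(length(stream$values),
            as.integer(floor((window[2] - stream$t0) * stream$fs + eps)) + 1L)
  if (k1 < k0) return(list(t = numeric(0), values = numeric(0)))
  idx <- k0:k1
  list(t = stream$t0 + (idx - 1L) / stream$fs, values = stream$values[idx])
}

#' Interpolated stream value at an arbitrary time
#'
#' Linear interpolation between the two bracketing samples; returns the edge
#' sample outside the recorded span and `NA` if a bracketing sample is missing.
#' @keywords internal
stream_value_at <- function(stream, t) {
  pos <- (t - stream$t0) * stream$fs + 1
  n <- length(stream$values)
  if (pos <= 1) return(stream$values[1L])
  if (pos >= n) return(stream$values[n])
  k <- floor(pos)
  w <- pos - k
  if (w < 1e-9) return(stream$values[k])
  stream$values[k] * (1 - w) + stream$values[k + 1L] * w
}
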