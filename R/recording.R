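#' Cuff event annotations for a vascular occlusion test
#'
#' Times (absolute seconds on the recording clock) of the protocol landmarks:
#' optional light-contraction onset, cuff inflation, cuff release, and the end
#' of the recording.
#'
#' @param t_inflate Cuff inflation time (s).
#' @param t_release Cuff release time (s); must exceed `t_inflate`.
#' @param end_time Recording end (s); must exceed `t_release`.
#' @param t_contract Optional light-contraction onset (s); must precede
#'   `t_inflate` when given. Use `NA` when the protocol had no contraction.
#' @return An object of class `cuff_events`.
#' @export
cuff_events <- function(t_inflate, t_release, end_time, t_contract = NA_real_) {
  ev <- list(
    t_contract = as.numeric(t_contract),
    t_inflate = as.numeric(t_inflate),
    t_release = as.numeric(t_release),
    end_time = as.numeric(end_time)
  )
  if (!is.finite(ev$t_inflate) || !is.finite(ev$t_release) || !is.finite(ev$end_time))
    stop("cuff events: t_inflate, t_release and end_time must be finite", call. = FALSE)
  if (!(ev$t_inflate < ev$t_release))
    stop("cuff events out of order: t_inflate must precede t_release", call. = FALSE)
  if (!(ev$t_release < ev$end_time))
    stop("cuff events out of order: t_release must precede end_time", call. = FALSE)
  if (is.finite(ev$t_contract) && !(ev$t_contract < ev$t_inflate))
    stop("cuff events out of order: t_contract must precede t_inflate", call. = FALSE)
  structure(ev, class = "cuff_events")
}

#' Subject metadata
#'
#' @param subject_id Subject identifier string.
#' @param group Group label, `"climber"` or `"nonclimber"`.
#' @param notes Optional free text.
#' @return An object of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, group = c("climber", "nonclimber"),
                         notes = "") {
  group <- match.arg(group)
  structure(
    list(subject_id = as.character(subject_id), group = group,
         notes = as.character(notes)),
    class = "subject_meta"
  )
}

#' A multi-rate vascular occlusion test recording
#'
#' Bundles the channel streams of one subject (NIRS chromophores at their
#' native rate, DCS blood flow index at its own rate, plus any derived
#' channels) with the cuff event annotations and subject metadata. A usable
#' recording carries at least the two NIRS chromophores or at least a BFI
#' stream.
#'
#' @param streams List of [channel_stream()] objects; names are taken from the
#'   streams themselves.
#' @param events A [cuff_events()] object.
#' @param meta A [subject_meta()] object.
#' @return An object of class `vot_recording`.
#' @seealso [validate_recording()] for structural checks,
#'   [preprocess_recording()], [extract_features()].
#' @export
vot_recording <- function(streams, events, meta = subject_meta("anonymous")) {
  if (inherits(streams, "channel_stream")) streams <- list(streams)
  if (length(streams) == 0L) stop("no channels", call. = FALSE)
  ok <- vapply(streams, inherits, logical(1), "channel_stream")
  if (!all(ok)) stop("streams must all be channel_stream objects", call. = FALSE)
  names(streams) <- vapply(streams, `[[`, character(1), "name")
  if (anyDuplicated(names(streams)))
    stop("duplicate channel names in recording", call. = FALSE)
  if (!inherits(events, "cuff_events")) stop("events must be cuff_events", call. = FALSE)
  if (!inherits(meta, "subject_meta")) stop("meta must be subject_meta", call. = FALSE)
  has_nirs <- all(c("O2HB", "HHB") %in% names(streams))
  has_dcs <- "BFI" %in% names(streams)
  if (!has_nirs && !has_dcs)
    stop("recording must contain O2HB and HHB, or BFI", call. = FALSE)
  structure(list(meta = meta, streams = streams, events = events),
            class = "vot_recording")
}

#' @export
print.vot_recording <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<vot_recording> subject %s (%s)\n", x$meta$subject_id, x$meta$group))
  cat(sprintf("  events: inflate %.1f s, release %.1f s, end %.1f s%s\n",
              ev$t_inflate, ev$t_release, ev$end_time,
              if (is.finite(ev$t_contract))
                sprintf(", contraction %.1f s", ev$t_contract) else ""))
  for (s in x$streams)
    cat(sprintf("  %-6s %8s  fs = %5.1f Hz  n = %d\n",
                s$name, paste0("[", s$unit, "]"), s$fs, length(s$values)))
  invisible(x)
}

#' Structural validation of a VOT recording
#'
#' Checks the invariants a recording must satisfy before analysis: event
#' ordering, stream coverage of the baseline window (at least `ba_min_s`
#' seconds before inflation) and of the post-release window (at least
#' `hy_min_s` seconds or to the end of the recording), and the absence of
#' missing-data runs longer than `gap_max_s` inside the occlusion and
#' hyperemia phases.
#'
#' Findings are reported, not raised: an empty character vector means the
#' recording is clean. Finding order is deterministic (by stream name, then
#' check).
#'
#' @param rec A [vot_recording()].
#' @param ba_min_s Minimum required pre-inflation coverage (s), default 60.
#' @param hy_min_s Minimum required post-release coverage (s), default 180.
#' @param gap_max_s Longest tolerated missing run inside OC/HY (s), default 1.
#' @return Character vector of findings (empty if valid).
#' @export
validate_recording <- function(rec, ba_min_s = 60, hy_min_s = 180, gap_max_s = 1) {
  stopifnot(inherits(rec, "vot_recording"))
  ev <- rec$events
  findings <- character(0)
  hy_end <- min(ev$t_release + hy_min_s, ev$end_time)
  for (nm in sort(names(rec$streams))) {
    s <- rec$streams[[nm]]
    tt <- range(stream_times(s))
    tol <- 1 / s$fs  # edge sample may sit just inside the nominal window
    if (tt[1] > ev$t_inflate - ba_min_s + tol)
      findings <- c(findings, sprintf(
        "%s: baseline window shorter than %g s (stream starts %.2f s before inflation)",
        nm, ba_min_s, ev$t_inflate - tt[1]))
    if (tt[2] < hy_end - tol)
      findings <- c(findings, sprintf(
        "%s: post-release coverage %.2f s, expected %.2f s",
        nm, max(0, tt[2] - ev$t_release), hy_end - ev$t_release))
    for (ph in list(c("OC", ev$t_inflate, ev$t_release),
                    c("HY", ev$t_release, hy_end))) {
      w <- stream_window(s, as.numeric(ph[2:3]))
      if (length(w$values) == 0L) next
      gap <- .longest_na_run(w$values) / s$fs
      if (gap > gap_max_s)
        findings <- c(findings, sprintf(
          "%s: gap of %.2f s in %s phase exceeds %g s", nm, gap, ph[1], gap_max_s))
    }
  }
  findings
}

.longest_na_run <- function(x) {
  if (!anyNA(x)) return(0L)
  r <- rle(is.na(x))
  max(r$lengths[r$values])
}
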