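#' Read a VOT recording from disk
#'
#' A recording lives in a directory holding one `recording.json` sidecar plus
#' one RFC-4180 CSV per stream group (streams sharing a sampling rate and
#' start time). The sidecar carries subject metadata, cuff events, and for
#' every CSV the sampling rate, start time, and the channel behind each
#' column. The CSV's first column is `time_s` (absolute seconds); remaining
#' columns are samples, with empty cells marking missing values.
#'
#' @param path Directory containing `recording.json`, or the path of the
#'   sidecar itself.
#' @return A validated [vot_recording()].
#' @seealso [write_recording()] for the emitting side of the format.
#' @export
read_recording <- function(path) {
  sidecar <- if (dir.exists(path)) file.path(path, "recording.json") else path
  if (!file.exists(sidecar))
    stop("no recording sidecar at ", sidecar, call. = FALSE)
  meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  for (field in c("subject_id", "group", "events", "files"))
    if (is.null(meta[[field]]))
      stop(sidecar, ": missing field '", field, "'", call. = FALSE)
  ev <- meta$events
  for (field in c("t_inflate", "t_release", "end_time"))
    if (is.null(ev[[field]]))
      stop(sidecar, ": events missing field '", field, "'", call. = FALSE)
  events <- tryCatch(
    cuff_events(ev$t_inflate, ev$t_release, ev$end_time,
                if (is.null(ev$t_contract)) NA_real_ else ev$t_contract),
    error = function(e) stop(sidecar, ": ", conditionMessage(e), call. = FALSE))

  streams <- list()
  base <- dirname(sidecar)
  for (fd in meta$files) {
    csv <- file.path(base, fd$file)
    if (!file.exists(csv)) stop("missing stream file ", csv, call. = FALSE)
    if (is.null(fd$fs) || is.null(fd$channels))
      stop(sidecar, ": file entry for '", fd$file,
           "' needs 'fs' and 'channels'", call. = FALSE)
    tab <- utils::read.csv(csv, check.names = FALSE)
    if (!"time_s" %in% names(tab))
      stop(csv, ": missing required column 'time_s'", call. = FALSE)
    t0 <- if (!is.null(fd$t0)) fd$t0 else tab$time_s[1L]
    for (ch in fd$channels) {
      if (is.null(ch$column) || is.null(ch$name))
        stop(sidecar, ": channel entries need 'column' and 'name'", call. = FALSE)
      if (!ch$column %in% names(tab))
        stop(csv, ": missing required column '", ch$column, "'", call. = FALSE)
      streams[[length(streams) + 1L]] <- channel_stream(
        ch$name, tab[[ch$column]], fs = fd$fs, t0 = t0,
        unit = if (is.null(ch$unit)) NULL else ch$unit)
    }
  }
  vot_recording(
    streams, events,
    subject_meta(meta$subject_id, meta$group,
                 if (is.null(meta$notes)) "" else meta$notes))
}

#' Write a VOT recording to disk
#'
#' Emits the on-disk layout consumed by [read_recording()]: one CSV per
#' (sampling rate, start time) stream group plus a `recording.json` sidecar.
#' Values are written with `digits` significant digits, so a write/read
#' round trip reproduces the recording to that precision.
#'
#' @param rec A [vot_recording()].
#' @param path Output directory (created if absent).
#' @param digits Significant digits for sample values (default 10).
#' @return Invisibly, the sidecar path.
#' @export
write_recording <- function(rec, path, digits = 10) {
  stopifnot(inherits(rec, "vot_recording"))
  if (length(rec$streams) == 0L) stop("no channels", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory ", path, call. = FALSE)

  key <- vapply(rec$streams, function(s) sprintf("%.9g@%.9g", s$fs, s$t0), character(1))
  files <- list()
  for (k in unique(key)) {
    members <- rec$streams[key == k]
    fs <- members[[1L]]$fs
    t0 <- members[[1L]]$t0
    n <- max(vapply(members, function(s) length(s$values), integer(1)))
    fname <- sprintf("streams_%shz%s.csv", format(fs),
                     if (sum(unique(key) == k) > 1 || match(k, unique(key)) > 1)
                       paste0("_", match(k, unique(key))) else "")
    cols <- c(list(time_s = sprintf("%.6f", t0 + (seq_len(n) - 1L) / fs)),
              lapply(members, function(s) {
                v <- c(s$values, rep(NA_real_, n - length(s$values)))
                ifelse(is.na(v), "", formatC(signif(v, digits), digits = digits,
                                             format = "g"))
              }))
    names(cols) <- c("time_s", names(members))
    utils::write.csv(as.data.frame(cols, check.names = FALSE),
                     file.path(path, fname), row.names = FALSE, quote = FALSE)
    files[[length(files) + 1L]] <- list(
      file = fname, fs = fs, t0 = t0,
      channels = lapply(members, function(s)
        list(column = s$name, name = s$name, unit = s$unit)))
  }
  ev <- rec$events
  sidecar <- list(
    subject_id = rec$meta$subject_id,
    group = rec$meta$group,
    notes = rec$meta$notes,
    events = list(
      t_contract = if (is.finite(ev$t_contract)) ev$t_contract else NULL,
      t_inflate = ev$t_inflate, t_release = ev$t_release,
      end_time = ev$end_time),
    files = unname(files))
  out <- file.path(path, "recording.json")
  jsonlite::write_json(sidecar, out, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
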