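#' Run the full VOT analysis over a cohort
#'
#' Orchestrates validate, preprocess, extract and the group statistics for
#' every subject of a cohort, writing `features.csv`, `report.csv` and a
#' run log (configuration echo plus one line per subject and stage) to the
#' output directory. Inputs can be a directory of per-subject recording
#' folders (see [read_recording()]) or an in-memory list of
#' [vot_recording()]s.
#'
#' @param input Cohort directory or list of recordings.
#' @param output_dir Directory for outputs (created if absent).
#' @param filter A [filter_spec()].
#' @param dcs_out_fs DCS analysis rate (Hz).
#' @param ba_window,hy_window,ba_guard,oc_slope_s,hy_slope_s,rbf_tail_s
#'   Feature-extraction windows, see [extract_features()].
#' @param groups Group labels, reference group first.
#' @param transform_policy,family_map,alpha See [run_family_analysis()].
#' @param skip_invalid Skip subjects that fail validation or extraction
#'   (with a warning) instead of failing the run.
#' @return Invisibly, a list with `features` (data frame), `report`
#'   (a `vot_report`), `table` (the rendered [make_report()] data frame)
#'   and the output paths.
#' @export
run_pipeline <- function(input, output_dir,
                         filter = filter_spec(), dcs_out_fs = 1,
                         ba_window = 60, hy_window = 180, ba_guard = 15,
                         oc_slope_s = 20, hy_slope_s = 10, rbf_tail_s = 10,
                         groups = c("climber", "nonclimber"),
                         transform_policy = default_transform_policy(),
                         family_map = default_family_map(),
                         alpha = 0.05, skip_invalid = FALSE) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(output_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  logline <- function(...) writeLines(paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                             " ", sprintf(...)), con)
  logline("votkit %s", as.character(utils::packageVersion("votkit")))
  logline("config: filter[f_pass=%g,f_stop=%g,stop_atten=%g] dcs_out_fs=%g ba_window=%g hy_window=%g ba_guard=%g oc_slope_s=%g hy_slope_s=%g rbf_tail_s=%g alpha=%g",
          filter$f_pass, filter$f_stop, filter$stop_atten, dcs_out_fs,
          ba_window, hy_window, ba_guard, oc_slope_s, hy_slope_s, rbf_tail_s,
          alpha)

  recs <- if (is.character(input)) {
    dirs <- sort(list.dirs(input, recursive = FALSE))
    dirs <- dirs[file.exists(file.path(dirs, "recording.json"))]
    if (length(dirs) == 0L) stop("no recordings found under ", input, call. = FALSE)
    stats::setNames(lapply(dirs, function(d) d), basename(dirs))
  } else input

  rows <- list()
  for (nm in names(recs)) {
    res <- tryCatch({
      rec <- recs[[nm]]
      if (is.character(rec)) rec <- read_recording(rec)
      findings <- validate_recording(rec, ba_min_s = ba_window,
                                     hy_min_s = hy_window)
      for (f in findings) logline("subject=%s stage=validate finding=%s", nm, f)
      if (length(findings) > 0L)
        stop("validation failed: ", findings[1L], call. = FALSE)
      pre <- preprocess_recording(rec, filter, dcs_out_fs)
      fs <- extract_features(pre, ba_window, hy_window, ba_guard,
                             oc_slope_s, hy_slope_s, rbf_tail_s)
      for (f in attr(fs, "findings"))
        logline("subject=%s stage=extract finding=%s", nm, f)
      logline("subject=%s stage=extract ok", nm)
      cbind(data.frame(subject_id = attr(fs, "subject_id"),
                       group = attr(fs, "group"), stringsAsFactors = FALSE),
            as.data.frame(lapply(fs, as.numeric)))
    }, error = function(e) {
      logline("subject=%s stage=failed error=%s", nm, conditionMessage(e))
      if (!skip_invalid)
        stop("subject ", nm, ": ", conditionMessage(e), call. = FALSE)
      warning("skipping subject ", nm, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(res)) rows[[nm]] <- res
  }
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  utils::write.csv(features, file.path(output_dir, "features.csv"),
                   row.names = FALSE)
  logline("features: %d subjects", nrow(features))

  report <- run_family_analysis(features, groups, transform_policy,
                                family_map, alpha)
  tab <- make_report(features, report)
  utils::write.csv(tab, file.path(output_dir, "report.csv"), row.names = FALSE)
  logline("report: %d variables, %d significant", nrow(tab),
          sum(tab$significant == "*"))
  invisible(list(features = features, report = report, table = tab,
                 features_path = file.path(output_dir, "features.csv"),
                 report_path = file.path(output_dir, "report.csv"),
                 log_path = log_path))
}

#' Render the group-comparison table
#'
#' Produces the human-readable summary in the layout of the study's results
#' table: one row per variable with each group's mean and SD, the raw and
#' family-adjusted p-values, Cohen's d, the transform applied, and a `*`
#' marker on variables whose adjusted p-value reaches the significance
#' level.
#'
#' @param features Cohort feature table (used only for column order).
#' @param report A [run_family_analysis()] result.
#' @return Data frame with character summary columns.
#' @export
make_report <- function(features, report) {
  pw <- report$pairwise
  if (is.null(pw) || nrow(pw) == 0L)
    return(data.frame(variable = character(0), group1 = character(0),
                      group2 = character(0), p_raw = character(0),
                      p_adj = character(0), d = character(0),
                      transform = character(0), significant = character(0)))
  msd <- function(m, s) sprintf("%.3g ± %.3g", m, s)
  out <- data.frame(
    variable = pw$variable,
    group1 = msd(pw$mean1, pw$sd1),
    group2 = msd(pw$mean2, pw$sd2),
    test = pw$test,
    transform = pw$transform,
    p_raw = sprintf("%.4f", pw$p_raw),
    p_adj = sprintf("%.4f", pw$p_adj),
    d = ifelse(is.na(pw$d), "", sprintf("%.3f", pw$d)),
    significant = ifelse(!is.na(pw$p_adj) & pw$p_adj <= report$alpha, "*", ""),
    stringsAsFactors = FALSE)
  names(out)[2:3] <- report$groups
  out
}
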