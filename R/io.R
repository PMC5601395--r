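# CSV writers and structured logging.  All outputs are plain text: tidy CSV
# for trajectories and event logs, YAML for run metadata, so every run is
# grep-able and bit-reproducible from its own metadata.

.format_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.15g", x))
}

.write_csv <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) .format_num(col) else as.character(col)
  })
  out <- do.call(cbind, cols)
  utils::write.table(rbind(names(df), out), file = path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE,
                     eol = "\r\n")
  invisible(path)
}

#' Write a simulation trajectory as CSV
#'
#' RFC-4180 CSV with the fixed column set of the engine grid
#' (`time_h, ldl_plasma_nmol_l, c_met_ng_ml, wss_pa, lumen_radius_mm,
#' atheroma_volume_mm3, pct_tav`), floats at 15 significant digits, header
#' always present (header-only file for an empty grid).
#'
#' @param result a `simulation_result`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(result, path) {
  .write_csv(result$grid, path)
}

#' Write the event log as CSV
#'
#' One row per event (planned doses with their taken flag as `value`,
#' growth transition, occlusion), sorted by time.
#'
#' @inheritParams write_timeseries
#' @export
write_events <- function(result, path) {
  ev <- result$events[order(result$events$time_h), , drop = FALSE]
  .write_csv(ev, path)
}

#' Write run metadata as YAML
#'
#' Serializes the fully resolved configuration (parameters in natural units,
#' regimen, adherence specification and realized trace, solver settings,
#' transition/occlusion times), sufficient to re-run the scenario
#' bit-identically.
#'
#' @inheritParams write_timeseries
#' @export
write_run_metadata <- function(result, path) {
  md <- result$metadata
  doc <- list(
    athero = unclass(md$params$athero),
    pkpd = unclass(md$params$pkpd)[setdiff(names(md$params$pkpd), "K_out")],
    regimen = if (is.null(md$regimen)) NULL else unclass(md$regimen),
    adherence = if (is.null(md$adherence)) NULL else unclass(md$adherence),
    engine = unclass(md$settings),
    realized = list(
      n_planned = md$n_planned,
      n_taken = md$n_taken,
      total_dose_mg = md$total_dose_mg,
      trace = if (is.null(md$trace)) NULL else as.integer(md$trace),
      transition_time_h = if (is.na(md$transition_time_h)) NULL else
        md$transition_time_h,
      occlusion_time_h = if (is.na(md$occlusion_time_h)) NULL else
        md$occlusion_time_h
    )
  )
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' Read a trajectory CSV written by [write_timeseries()]
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# leveled logging to stderr: per-dose detail at debug, phase transitions and
# calibration summaries at info
.log_level <- new.env(parent = emptyenv())
.log_level$threshold <- "info"
.log_ranks <- c(debug = 1L, info = 2L, warn = 3L)

#' Set the logging threshold
#' @param level one of "debug", "info", "warn".
#' @export
set_log_level <- function(level = c("info", "debug", "warn")) {
  .log_level$threshold <- match.arg(level)
  invisible(.log_level$threshold)
}

qsp_log <- function(level, fmt, ...) {
  if (.log_ranks[[level]] >= .log_ranks[[.log_level$threshold]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}
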