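#' Read and write the package's CSV/JSON file contracts
#'
#' Stable plain-text formats shared by the command-line interface and the
#' simulator: eye traces (`t_ms,x,y`), calibration schedules
#' (`epoch,x_deg,y_deg,t_start_ms,t_end_ms`), patch-stimulus events
#' (`t_onset_ms,row,col,duration_ms`), spike timestamps (`channel,t_ms`),
#' saccade tables, and calibration results as JSON. Readers fail with a
#' message naming the offending file and column before any computation
#' runs.
#'
#' @param path File path.
#' @param unit,rate_hz Unit tag and sampling rate for the trace (rate is
#'   inferred from the timestamps when omitted).
#' @param trace,schedule,events,spikes,saccades,result Objects to
#'   serialize.
#' @return Readers return the corresponding package object; writers return
#'   the path invisibly.
#' @name freeview_io
NULL

check_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    fv_input_error(sprintf("%s: missing column '%s'", path, missing[1]))
  df
}

#' @rdname freeview_io
#' @export
read_eye_trace <- function(path, unit = c("volts", "degrees"),
                           rate_hz = NULL) {
  unit <- match.arg(unit)
  df <- read.csv(path)
  check_columns(df, c("t_ms", "x", "y"), path)
  eye_trace(df$t_ms, df$x, df$y, unit = unit, rate_hz = rate_hz)
}

#' @rdname freeview_io
#' @export
write_eye_trace <- function(trace, path) {
  write.csv(data.frame(t_ms = trace$t, x = trace$x, y = trace$y),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname freeview_io
#' @export
read_schedule <- function(path) {
  df <- read.csv(path)
  check_columns(df, c("epoch", "x_deg", "y_deg", "t_start_ms", "t_end_ms"),
                path)
  class(df) <- c("calibration_schedule", "data.frame")
  df
}

#' @rdname freeview_io
#' @export
write_schedule <- function(schedule, path) {
  write.csv(as.data.frame(schedule)[, c("epoch", "x_deg", "y_deg",
                                        "t_start_ms", "t_end_ms")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname freeview_io
#' @export
read_events <- function(path) {
  df <- read.csv(path)
  check_columns(df, c("t_onset_ms", "row", "col"), path)
  df
}

#' @rdname freeview_io
#' @export
write_events <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname freeview_io
#' @export
read_spikes <- function(path) {
  df <- read.csv(path)
  check_columns(df, c("channel", "t_ms"), path)
  split(df$t_ms, df$channel) |> lapply(sort)
}

#' @rdname freeview_io
#' @export
write_spikes <- function(spikes, path) {
  df <- data.frame(
    channel = rep(names(spikes), lengths(spikes)),
    t_ms = unlist(spikes, use.names = FALSE)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname freeview_io
#' @export
write_saccades <- function(saccades, path) {
  cols <- c("t_onset", "t_offset", "x0", "y0", "x1", "y1", "amplitude",
            "direction", "peak_velocity", "peak_accel")
  extra <- intersect(c("dir_bin", "amp_bin"), names(saccades))
  out <- saccades[, c(cols, extra)]
  names(out)[1:2] <- c("t_onset_ms", "t_offset_ms")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname freeview_io
#' @export
read_saccades <- function(path) {
  df <- read.csv(path)
  check_columns(df, c("t_onset_ms", "t_offset_ms", "amplitude", "direction"),
                path)
  names(df)[match(c("t_onset_ms", "t_offset_ms"), names(df))] <-
    c("t_onset", "t_offset")
  df
}

#' @rdname freeview_io
#' @export
write_calibration <- function(result, path) {
  jsonlite::write_json(
    list(cal_x = result$cal_x, cal_y = result$cal_y,
         centers = result$centers, pooled_sd_deg = result$pooled_sd_deg,
         n_epochs_used = result$n_epochs_used),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname freeview_io
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "calibration_result")
}
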