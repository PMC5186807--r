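#' Telemetry stream columns
#'
#' A telemetry stream is a tibble with one row per sample and the columns
#' below, plus attributes `driver_id`, `session_id` and `scenario_ref`.
#' Sampling need not be uniform; the detection engine works from timestamp
#' differences only.
#'
#' \describe{
#'   \item{t}{seconds from run start, strictly increasing}
#'   \item{s}{longitudinal position of the vehicle front, metres,
#'     non-decreasing}
#'   \item{lateral_offset}{signed metres from lane centre; positive toward
#'     the left lane line}
#'   \item{speed}{km/h, non-negative}
#'   \item{accel_pedal,brake_pedal}{pedal displacement fractions in 0-1}
#'   \item{turn_signal}{`"none"`, `"left"` or `"right"`}
#'   \item{head_yaw}{degrees; 0 straight ahead, positive leftward}
#'   \item{lane_index}{integer, 0 = rightmost lane}
#'   \item{lead_gap}{bumper-to-bumper metres to the lead vehicle, `NA` when
#'     no lead is present}
#' }
#'
#' @name telemetry-format
NULL

telemetry_columns <- function() {
  c("t", "s", "lateral_offset", "speed", "accel_pedal", "brake_pedal",
    "turn_signal", "head_yaw", "lane_index", "lead_gap")
}

#' Construct a telemetry stream
#'
#' Wraps a data frame of samples (see [telemetry-format]) with run metadata
#' and checks the hard invariants (non-empty, strictly increasing time).
#'
#' @param samples Data frame with the telemetry columns.
#' @param driver_id,session_id,scenario_ref Run metadata strings.
#' @return A tibble with telemetry attributes.
#' @export
telemetry_stream <- function(samples, driver_id = "d1", session_id = "s1",
                             scenario_ref = "reference") {
  missing <- setdiff(telemetry_columns(), names(samples))
  if (length(missing) > 0) {
    stop("missing telemetry column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(samples) == 0) stop("no samples", call. = FALSE)
  stream <- as_tibble(samples)[, telemetry_columns()]
  attr(stream, "driver_id") <- driver_id
  attr(stream, "session_id") <- session_id
  attr(stream, "scenario_ref") <- scenario_ref
  stream
}

#' Write a telemetry stream to CSV
#'
#' One row per sample; run metadata is kept in `#`-prefixed header lines so
#' the file round-trips losslessly through [read_telemetry()]. Numeric
#' values are written in shortest round-trip representation.
#'
#' @param stream A telemetry stream.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_telemetry <- function(stream, path) {
  meta <- sprintf("# %s: %s", c("driver_id", "session_id", "scenario_ref"),
                  c(attr(stream, "driver_id") %||% "unknown",
                    attr(stream, "session_id") %||% "unknown",
                    attr(stream, "scenario_ref") %||% "unknown"))
  writeLines(meta, path)
  readr::write_csv(as_tibble(stream), path, na = "NA", append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a telemetry stream from CSV
#'
#' Parses a file written by [write_telemetry()] (or any CSV with the
#' documented columns). Malformed input is reported with the offending
#' file line: missing columns, an empty sample table, and non-monotone
#' time are all parse errors.
#'
#' @param path File to read.
#' @return A telemetry stream.
#' @export
read_telemetry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 10)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  meta <- list(driver_id = "unknown", session_id = "unknown",
               scenario_ref = "unknown")
  for (m in meta_lines) {
    kv <- regmatches(m, regexec("^#\\s*([a-z_]+):\\s*(.*)$", m))[[1]]
    if (length(kv) == 3 && kv[2] %in% names(meta)) meta[[kv[2]]] <- kv[3]
  }
  # base-R parsing: exact binary round trip of the shortest-representation
  # doubles that write_telemetry emits
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", na.strings = "NA",
                    stringsAsFactors = FALSE),
    error = function(e) {
      stop("parse error: ", conditionMessage(e), call. = FALSE)
    }
  )
  df <- as_tibble(df)
  if ("lane_index" %in% names(df)) df$lane_index <- as.integer(df$lane_index)
  if ("turn_signal" %in% names(df)) {
    df$turn_signal <- as.character(df$turn_signal)
  }
  if ("lead_gap" %in% names(df)) df$lead_gap <- as.numeric(df$lead_gap)
  missing <- setdiff(telemetry_columns(), names(df))
  if (length(missing) > 0) {
    stop("parse error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("parse error: no samples", call. = FALSE)
  bad <- which(diff(df$t) <= 0)
  if (length(bad) > 0) {
    # file line number: comment lines + header + 1-based data row
    line_no <- length(meta_lines) + 1 + bad[1] + 1
    stop("parse error: time not strictly increasing at line ", line_no,
         call. = FALSE)
  }
  telemetry_stream(df, meta$driver_id, meta$session_id, meta$scenario_ref)
}

#' Validate a telemetry stream against a scenario
#'
#' Checks stream invariants (strictly increasing `t`, non-decreasing `s`,
#' non-negative speed, head yaw within +/-180 degrees, non-negative lead
#' gaps) and, when a scenario is supplied, that positions stay on the
#' route. Violations are returned as messages, not raised.
#'
#' @param stream A telemetry stream.
#' @param spec Optional `scenario_spec`.
#' @return Character vector of violation messages (empty if valid).
#' @export
validate_stream <- function(stream, spec = NULL) {
  v <- character()
  if (nrow(stream) == 0) return("stream has no samples")
  dup <- which(diff(stream$t) == 0)
  if (length(dup) > 0) {
    v <- c(v, paste0("duplicate timestamp at sample ", dup[1] + 1))
  }
  back <- which(diff(stream$t) < 0)
  if (length(back) > 0) {
    v <- c(v, paste0("time decreases at sample ", back[1] + 1))
  }
  if (any(diff(stream$s) < -1e-9)) {
    v <- c(v, paste0("position decreases at sample ",
                     which(diff(stream$s) < -1e-9)[1] + 1))
  }
  if (any(stream$speed < 0)) v <- c(v, "negative speed")
  if (any(abs(stream$head_yaw) > 180)) v <- c(v, "head yaw outside +/-180")
  if (any(!is.na(stream$lead_gap) & stream$lead_gap < 0)) {
    v <- c(v, "negative lead gap")
  }
  if (!all(stream$turn_signal %in% c("none", "left", "right"))) {
    v <- c(v, "turn_signal outside {none, left, right}")
  }
  if (!is.null(spec)) {
    over <- which(stream$s > spec$total_length)
    if (length(over) > 0) {
      v <- c(v, paste0("position ", stream$s[over[1]],
                       " beyond route end at sample ", over[1]))
    }
  }
  v
}

#' Resample a telemetry stream to a fixed rate
#'
#' Linear interpolation for continuous channels; previous-value carry for
#' the discrete channels (`turn_signal`, `lane_index`) and for lead-vehicle
#' presence. Used to demonstrate that detection counts are invariant to the
#' logging rate.
#'
#' @param stream A telemetry stream.
#' @param rate_hz Target sampling rate in Hz.
#' @return A telemetry stream at the new rate.
#' @export
resample_telemetry <- function(stream, rate_hz) {
  t_new <- seq(stream$t[1], stream$t[nrow(stream)], by = 1 / rate_hz)
  lin <- function(y) stats::approx(stream$t, y, xout = t_new)$y
  step_chr <- function(y) {
    idx <- findInterval(t_new, stream$t)
    y[pmax(idx, 1)]
  }
  present <- !is.na(stream$lead_gap)
  gap_filled <- stream$lead_gap
  if (any(present) && any(!present)) {
    gap_filled[!present] <- stats::approx(
      stream$t[present], stream$lead_gap[present], xout = stream$t[!present],
      rule = 2
    )$y
  }
  out <- tibble(
    t = t_new,
    s = lin(stream$s),
    lateral_offset = lin(stream$lateral_offset),
    speed = lin(stream$speed),
    accel_pedal = lin(stream$accel_pedal),
    brake_pedal = lin(stream$brake_pedal),
    turn_signal = step_chr(stream$turn_signal),
    head_yaw = lin(stream$head_yaw),
    lane_index = as.integer(step_chr(stream$lane_index)),
    lead_gap = ifelse(step_chr(present), lin(gap_filled), NA_real_)
  )
  telemetry_stream(out, attr(stream, "driver_id"),
                   attr(stream, "session_id"), attr(stream, "scenario_ref"))
}
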