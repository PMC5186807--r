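#' Detection configuration
#'
#' All numeric thresholds of the real-time driving-error engine. Every
#' threshold is a strict inequality on the violating side, so inputs exactly
#' at a threshold are compliant (a speed of limit + 10 km/h, a headway of
#' exactly 2 s, a lateral offset of exactly 17.5% of lane width never fire).
#'
#' @param speed_grace Tolerated excess over the zone limit, km/h.
#' @param speed_rewarn_window Seconds before a persisting speeding episode
#'   records a further error.
#' @param headway_threshold Minimum safe time headway to a lead vehicle, s.
#' @param tailgate_rewarn_window Seconds before a persisting tailgating
#'   episode records a further error.
#' @param weave_fraction Fraction of lane width beyond which lateral offset
#'   counts as off-centre (must be < 0.5).
#' @param weave_persistence Seconds the offset must stay beyond the
#'   threshold before a weaving error is recorded.
#' @param stop_speed Speed below which the vehicle counts as stopped, km/h.
#' @param stop_duration Seconds the stop must be sustained.
#' @param feedback_refractory Minimum seconds between emitted feedbacks;
#'   errors inside the window are recorded but silent.
#' @param blindspot_yaw Head-yaw magnitude (degrees) that counts as a
#'   blind-spot check toward the lane-change direction.
#' @param blindspot_window Seconds before a lane-boundary crossing within
#'   which the signal and the blind-spot check must occur.
#' @param visual_search_yaw Head-yaw magnitude (degrees) that counts as a
#'   left/right look during the stop-sign visual search.
#' @param approach_window Metres before a stop line that define the
#'   intersection approach.
#' @param count_rewarnings Count re-warnings within one continuing episode
#'   as additional errors (the default); set `FALSE` to count one error per
#'   episode.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(speed_grace = 10, speed_rewarn_window = 10,
                             headway_threshold = 2, tailgate_rewarn_window = 10,
                             weave_fraction = 0.175, weave_persistence = 10,
                             stop_speed = 1, stop_duration = 1,
                             feedback_refractory = 7,
                             blindspot_yaw = 45, blindspot_window = 3,
                             visual_search_yaw = 30, approach_window = 30,
                             count_rewarnings = TRUE) {
  cfg <- list(
    speed_grace = speed_grace, speed_rewarn_window = speed_rewarn_window,
    headway_threshold = headway_threshold,
    tailgate_rewarn_window = tailgate_rewarn_window,
    weave_fraction = weave_fraction, weave_persistence = weave_persistence,
    stop_speed = stop_speed, stop_duration = stop_duration,
    feedback_refractory = feedback_refractory,
    blindspot_yaw = blindspot_yaw, blindspot_window = blindspot_window,
    visual_search_yaw = visual_search_yaw, approach_window = approach_window,
    count_rewarnings = count_rewarnings
  )
  num <- cfg[setdiff(names(cfg), "count_rewarnings")]
  if (any(unlist(num) <= 0)) stop("all thresholds must be positive", call. = FALSE)
  if (weave_fraction >= 0.5) stop("weave_fraction must be < 0.5", call. = FALSE)
  structure(cfg, class = "detection_config")
}

empty_errors <- function() {
  tibble(kind = character(), t = numeric(), s = numeric(),
         detail = character())
}

error_rows <- function(kind, t, s, detail) {
  if (length(t) == 0) return(empty_errors())
  tibble(kind = kind, t = t, s = s, detail = detail)
}

# Episode bookkeeping for the continuous rules (speeding, tailgating):
# one error at each onset, then a further error every `rewarn` seconds
# while the violation persists. Returns sample indices of the emissions.
episode_emissions <- function(viol, t, rewarn, count_rewarnings = TRUE) {
  r <- rle(viol)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- integer()
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    out <- c(out, i0)
    if (count_rewarnings) {
      last <- t[i0]
      i <- i0
      while (TRUE) {
        nxt <- which(t[(i + 1):i1] >= last + rewarn)
        if (i + 1 > i1 || length(nxt) == 0) break
        i <- i + nxt[1]
        out <- c(out, i)
        last <- t[i]
      }
    }
  }
  out
}

# Persistence bookkeeping for weaving: an error each time the violation has
# lasted `persistence` seconds; the clock restarts after each emission and
# whenever the offset returns within bounds.
persistence_emissions <- function(viol, t, persistence) {
  r <- rle(viol)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- integer()
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    clock <- t[i0]
    i <- i0
    while (TRUE) {
      nxt <- which(t[i:i1] >= clock + persistence)
      if (length(nxt) == 0) break
      i <- i + nxt[1] - 1
      out <- c(out, i)
      clock <- t[i]
      if (i >= i1) break
    }
  }
  out
}

#' Detect speeding errors
#'
#' An error is recorded at each onset where speed first exceeds the zone
#' limit plus the grace (strictly), and again every re-warning window while
#' the violation persists. Dropping back to the limit-plus-grace boundary
#' (or below) ends the episode.
#'
#' @param stream A telemetry stream.
#' @param spec A `scenario_spec`.
#' @param config A [detection_config()].
#' @return Tibble of errors (`kind`, `t`, `s`, `detail`).
#' @export
detect_speeding <- function(stream, spec, config = detection_config()) {
  lim <- limit_at(spec, stream$s)
  viol <- stream$speed > lim + config$speed_grace
  idx <- episode_emissions(viol, stream$t, config$speed_rewarn_window,
                          config$count_rewarnings)
  error_rows("speeding", stream$t[idx], stream$s[idx],
             sprintf("%.1f km/h in %d zone", stream$speed[idx], lim[idx]))
}

#' Detect tailgating errors
#'
#' Time headway is the bumper-to-bumper gap divided by the follower's speed.
#' An error is recorded at each onset where the headway drops strictly below
#' the threshold while a lead vehicle is present, and again every re-warning
#' window while the episode persists. A standing vehicle (speed 0) has
#' undefined headway and is treated as compliant.
#'
#' @inheritParams detect_speeding
#' @return Tibble of errors.
#' @export
detect_tailgating <- function(stream, spec, config = detection_config()) {
  v_ms <- stream$speed / 3.6
  h <- ifelse(!is.na(stream$lead_gap) & v_ms > 0, stream$lead_gap / v_ms, Inf)
  viol <- h < config$headway_threshold
  idx <- episode_emissions(viol, stream$t, config$tailgate_rewarn_window,
                          config$count_rewarnings)
  error_rows("tailgating", stream$t[idx], stream$s[idx],
             sprintf("headway %.2f s", h[idx]))
}

#' Detect weaving errors
#'
#' A weaving error is recorded when the absolute lateral offset stays
#' strictly beyond `weave_fraction * lane_width` continuously for at least
#' `weave_persistence` seconds. Samples within +/-2 s of a lane-boundary
#' crossing are exempt (a lane change necessarily leaves the lane centre).
#' The persistence clock restarts after each emission and whenever the
#' offset returns within bounds.
#'
#' @inheritParams detect_speeding
#' @return Tibble of errors.
#' @export
detect_weaving <- function(stream, spec, config = detection_config()) {
  thr <- config$weave_fraction * spec$lane_width
  viol <- abs(stream$lateral_offset) > thr
  crossings <- lane_crossing_times(stream)
  for (tc in crossings) {
    viol[stream$t >= tc - 2 & stream$t <= tc + 2] <- FALSE
  }
  idx <- persistence_emissions(viol, stream$t, config$weave_persistence)
  error_rows("weaving", stream$t[idx], stream$s[idx],
             sprintf("offset %.2f m (threshold %.4f m)",
                     stream$lateral_offset[idx], thr))
}

lane_crossing_times <- function(stream) {
  ch <- which(diff(stream$lane_index) != 0) + 1
  stream$t[ch]
}

#' Detect lane-change events and their omissions
#'
#' A lane-change event is logged at each change of `lane_index`,
#' timestamped at the boundary crossing. The event is `signaled` if the
#' correct-direction turn signal was active at some point in the
#' `blindspot_window` before the crossing, and `blindspot_checked` if head
#' yaw reached the blind-spot threshold toward the change direction in the
#' same window. An unsignaled event records a `signal_omission` error, an
#' unchecked one a `blindspot_omission`; both can fire for one event.
#'
#' @inheritParams detect_speeding
#' @return List with `events` (tibble: `t`, `s`, `direction`, `signaled`,
#'   `blindspot_checked`) and `errors` (tibble of errors).
#' @export
detect_lane_changes <- function(stream, spec, config = detection_config()) {
  ch <- which(diff(stream$lane_index) != 0) + 1
  events <- tibble(t = numeric(), s = numeric(), direction = character(),
                   signaled = logical(), blindspot_checked = logical())
  errors <- empty_errors()
  for (i in ch) {
    dir_left <- stream$lane_index[i] > stream$lane_index[i - 1]
    direction <- if (dir_left) "left" else "right"
    tc <- stream$t[i]
    win <- stream$t >= tc - config$blindspot_window & stream$t < tc
    signaled <- any(stream$turn_signal[win] == direction)
    yaw <- stream$head_yaw[win]
    checked <- if (dir_left) any(yaw >= config$blindspot_yaw)
               else any(yaw <= -config$blindspot_yaw)
    events <- dplyr::bind_rows(events, tibble(
      t = tc, s = stream$s[i], direction = direction,
      signaled = signaled, blindspot_checked = checked
    ))
    if (!signaled) {
      errors <- dplyr::bind_rows(errors, error_rows(
        "signal_omission", tc, stream$s[i],
        paste0("unsignaled ", direction, " lane change")))
    }
    if (!checked) {
      errors <- dplyr::bind_rows(errors, error_rows(
        "blindspot_omission", tc, stream$s[i],
        paste0("no blind-spot check before ", direction, " lane change")))
    }
  }
  list(events = events, errors = errors)
}

# Runs of speed < stop_speed sustained >= stop_duration, as index ranges.
stop_runs <- function(stream, config) {
  stopped <- stream$speed < config$stop_speed
  r <- rle(stopped)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (stream$t[ends] - stream$t[starts]) >= config$stop_duration
  tibble(i0 = starts[keep], i1 = ends[keep])
}

# First sample index at or past a position, NA if never reached.
crossing_index <- function(s, position) {
  idx <- which(s >= position)
  if (length(idx) == 0) NA_integer_ else idx[1]
}

#' Detect stop-sign control errors
#'
#' Per stop-sign intersection, a complete stop is a sustained
#' below-threshold speed with the vehicle front inside the approach window
#' (`[stop line - approach_window, stop line]`). One `stop_control` error is
#' recorded if no complete stop occurred before crossing, or if the only
#' stop occurred with the front beyond the line. Errors are stamped at the
#' sample where the vehicle clears the intersection.
#'
#' @inheritParams detect_speeding
#' @return Tibble of errors.
#' @export
detect_stop_sign_control <- function(stream, spec, config = detection_config()) {
  runs <- stop_runs(stream, config)
  errors <- empty_errors()
  signs <- spec$intersections[spec$intersections$control == "stop-sign", ]
  for (i in seq_len(nrow(signs))) {
    line <- signs$position[i]
    exit_idx <- crossing_index(stream$s, line + signs$intersection_length[i])
    if (is.na(exit_idx)) next # never crossed
    # a stop is located where the sustained sub-threshold period begins
    in_window <- runs$i0 <= exit_idx &
      stream$s[runs$i0] >= line - config$approach_window &
      stream$s[runs$i0] <= line
    if (!any(in_window)) {
      overshoot <- runs$i0 <= exit_idx &
        stream$s[runs$i0] > line &
        stream$s[runs$i0] <= line + signs$intersection_length[i]
      detail <- if (any(overshoot)) "stopped beyond the stop line"
                else "no complete stop at stop sign"
      errors <- dplyr::bind_rows(errors, error_rows(
        "stop_control", stream$t[exit_idx], stream$s[exit_idx], detail))
    }
  }
  errors
}

#' Detect visual-search errors at stop-sign intersections
#'
#' On the approach to each stop sign (from `stop line - approach_window` to
#' the stop line), the driver must look left (head yaw at or beyond
#' `+visual_search_yaw`), right (at or beyond `-visual_search_yaw`), and
#' ahead between the two extremes, in either order. A missing component
#' records one `visual_search` error, stamped at the sample where the
#' vehicle clears the intersection.
#'
#' @inheritParams detect_speeding
#' @return Tibble of errors.
#' @export
detect_visual_search <- function(stream, spec, config = detection_config()) {
  errors <- empty_errors()
  signs <- spec$intersections[spec$intersections$control == "stop-sign", ]
  for (i in seq_len(nrow(signs))) {
    line <- signs$position[i]
    exit_idx <- crossing_index(stream$s, line + signs$intersection_length[i])
    if (is.na(exit_idx)) next
    win <- which(stream$s >= line - config$approach_window & stream$s <= line)
    yaw <- stream$head_yaw[win]
    thr <- config$visual_search_yaw
    iL <- which(yaw >= thr)[1]
    iR <- which(yaw <= -thr)[1]
    ok <- FALSE
    if (!is.na(iL) && !is.na(iR)) {
      between <- yaw[min(iL, iR):max(iL, iR)]
      ok <- any(abs(between) < thr)
    }
    if (!ok) {
      errors <- dplyr::bind_rows(errors, error_rows(
        "visual_search", stream$t[exit_idx], stream$s[exit_idx],
        "incomplete left-ahead-right scan before stop-sign intersection"))
    }
  }
  errors
}

#' Detect red-light control errors
#'
#' The permissive yellow rule: entering the intersection at any point during
#' yellow is legal, but if the light is red when the vehicle front passes
#' the intersection midpoint and the vehicle entered on yellow or red, one
#' `redlight_control` error is recorded at the midpoint crossing.
#' Additionally, stopping (sustained sub-threshold speed) with the front
#' beyond the stop line but inside the intersection while the light is red
#' records a `redlight_control` error for stopping beyond the line.
#'
#' @inheritParams detect_speeding
#' @return Tibble of errors.
#' @export
detect_redlight_control <- function(stream, spec, config = detection_config()) {
  errors <- empty_errors()
  lights <- spec$intersections[spec$intersections$control == "traffic-light", ]
  runs <- stop_runs(stream, config)
  for (i in seq_len(nrow(lights))) {
    line <- lights$position[i]
    ilen <- lights$intersection_length[i]
    sched <- lights$light_schedule[[i]]
    if (is.null(sched)) next
    entry_idx <- crossing_index(stream$s, line)
    mid_idx <- crossing_index(stream$s, line + ilen / 2)
    if (!is.na(entry_idx) && !is.na(mid_idx)) {
      entry_phase <- phase_at(sched, stream$t[entry_idx])
      mid_phase <- phase_at(sched, stream$t[mid_idx])
      if (mid_phase == "red" && entry_phase %in% c("yellow", "red")) {
        errors <- dplyr::bind_rows(errors, error_rows(
          "redlight_control", stream$t[mid_idx], stream$s[mid_idx],
          paste0("entered on ", entry_phase, ", red before midpoint")))
      }
    }
    beyond <- runs$i0[stream$s[runs$i0] > line &
                        stream$s[runs$i0] <= line + ilen]
    beyond <- beyond[phase_at(sched, stream$t[beyond]) == "red"]
    if (length(beyond) > 0) {
      errors <- dplyr::bind_rows(errors, error_rows(
        "redlight_control", stream$t[beyond[1]], stream$s[beyond[1]],
        "stopped beyond the stop line on red"))
    }
  }
  errors
}

#' Run the full detection engine over a telemetry stream
#'
#' Runs all eight detectors, merges their errors in time order, and applies
#' the feedback refractory: an error emits feedback only if at least
#' `feedback_refractory` seconds have elapsed since the last emitted
#' feedback (the first error always emits). Suppressed errors are still
#' recorded and counted; counts are therefore invariant to the refractory.
#'
#' @inheritParams detect_speeding
#' @return A `run_report`: list with `errors` (tibble with
#'   `feedback_emitted`), `counts` (named integer vector over the eight
#'   kinds), `duration` (s), and `lane_change_events`.
#' @export
run_engine <- function(stream, spec, config = detection_config()) {
  sv <- validate_stream(stream, spec)
  if (length(sv) > 0) {
    stop("invalid stream: ", paste(sv, collapse = "; "), call. = FALSE)
  }
  lc <- detect_lane_changes(stream, spec, config)
  errors <- dplyr::bind_rows(
    detect_speeding(stream, spec, config),
    detect_tailgating(stream, spec, config),
    detect_weaving(stream, spec, config),
    lc$errors,
    detect_stop_sign_control(stream, spec, config),
    detect_visual_search(stream, spec, config),
    detect_redlight_control(stream, spec, config)
  )
  errors$kind <- factor(errors$kind, levels = error_kinds())
  errors <- errors[order(errors$t, errors$kind), ]
  errors$kind <- as.character(errors$kind)
  emitted <- logical(nrow(errors))
  last_emit <- -Inf
  for (i in seq_len(nrow(errors))) {
    if (errors$t[i] - last_emit >= config$feedback_refractory) {
      emitted[i] <- TRUE
      last_emit <- errors$t[i]
    }
  }
  errors$feedback_emitted <- emitted
  errors <- errors[, c("kind", "t", "s", "feedback_emitted", "detail")]
  counts <- table(factor(errors$kind, levels = error_kinds()))
  counts <- stats::setNames(as.integer(counts), error_kinds())
  structure(
    list(
      errors = errors,
      counts = counts,
      duration = stream$t[nrow(stream)] - stream$t[1],
      lane_change_events = lc$events,
      driver_id = attr(stream, "driver_id"),
      session_id = attr(stream, "session_id")
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> driver ", x$driver_id %||% "?", ", session ",
      x$session_id %||% "?", "\n", sep = "")
  cat("  duration: ", round(x$duration, 1), " s; total errors: ",
      sum(x$counts), " (", sum(x$errors$feedback_emitted),
      " with feedback)\n", sep = "")
  nz <- x$counts[x$counts > 0]
  if (length(nz) > 0) {
    for (k in names(nz)) cat("  ", k, ": ", nz[k], "\n", sep = "")
  }
  cat("  lane changes: ", nrow(x$lane_change_events), "\n", sep = "")
  invisible(x)
}
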